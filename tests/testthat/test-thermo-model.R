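p <- turner_params()

test_that("parameter fixture is complete and sane", {
  expect_false(anyNA(p$stack))
  expect_true(all(diff(p$hairpin_init[3:30]) >= 0))
  expect_true(all(diff(p$bulge_init[1:30]) >= 0))
  expect_true(all(diff(p$internal_init[2:30]) >= 0))
  # stacking obeys the strand-reversal symmetry of the nearest-neighbor
  # model: stack[PQ, RS] == stack[rev(RS), rev(PQ)]
  rev_pair <- function(q) paste0(substr(q, 2, 2), substr(q, 1, 1))
  for (o in rownames(p$stack)) {
    for (i in colnames(p$stack)) {
      expect_equal(p$stack[o, i], p$stack[rev_pair(i), rev_pair(o)])
    }
  }
})

test_that("stacked-pair energy is a direct table lookup", {
  # helix CG / GC / CG: outer stack closes (1,12) over inner (2,11)
  y <- parse_dotbracket("((((....))))")
  x <- "CGCGAAAACGCG"
  loops <- decompose_loops(y)
  st <- loops[loops$kind == "stacked", ]
  v <- loop_free_energy(as.list(st[1, ]), x, p)
  expect_equal(v, p$stack["CG", "GC"])
})

test_that("multibranch energy follows the affine closed form", {
  # closing pair (1,26), two inner branches, 4 unpaired bases in the
  # loop; all pairs CG/GC so no AU/GU end penalties enter
  pairs <- rbind(c(1, 26), c(3, 9), c(4, 8), c(12, 18), c(13, 17))
  x <- paste(rep("A", 26), collapse = "")
  x <- "CACGAAACGGGCGAAAACGGGGAAAG"
  seqv <- strsplit(x, "")[[1]]
  seqv[c(1, 26)] <- c("C", "G"); seqv[c(3, 9)] <- c("C", "G")
  seqv[c(4, 8)] <- c("G", "C"); seqv[c(12, 18)] <- c("C", "G")
  seqv[c(13, 17)] <- c("G", "C")
  x <- paste(seqv, collapse = "")
  y <- rna_structure(pairs, 26)
  loops <- decompose_loops(y)
  mb <- loops[loops$kind == "multibranch", ]
  expect_equal(nrow(mb), 1L)
  n_unpaired <- sum(mb$runs[[1]][, 2] - mb$runs[[1]][, 1] + 1)
  expect_equal(n_unpaired, 10L)
  v <- loop_free_energy(as.list(mb[1, ]), x, p)
  expect_equal(v, p$multibranch[["a"]] + 3 * p$multibranch[["b"]] +
                 n_unpaired * p$multibranch[["c"]])
})

test_that("long loops extrapolate logarithmically beyond the table", {
  # hairpin of 40 unpaired bases closed by CG
  L <- 42
  x <- paste0("C", paste(rep("A", 40), collapse = ""), "G")
  y <- rna_structure(rbind(c(1, L)), L)
  hp <- decompose_loops(y)
  hp <- hp[hp$kind == "hairpin", ]
  v <- loop_free_energy(as.list(hp[1, ]), x, p)
  expected <- p$hairpin_init[30] + p$extrapolation * log(40 / 30) +
    p$terminal_mismatch["CG", "A", "A"]
  expect_equal(v, expected)
})

test_that("free energy is additive over independent domains", {
  x1 <- "GGGAAACCC"; db1 <- "(((...)))"
  x2 <- "GCGCAAAAGCGC"; db2 <- "((((....))))"
  e1 <- free_energy(x1, parse_dotbracket(db1), p)$total
  e2 <- free_energy(x2, parse_dotbracket(db2), p)$total
  joint <- free_energy(paste0(x1, x2),
                       parse_dotbracket(paste0(db1, db2)), p)$total
  expect_equal(joint, e1 + e2)
  # empty structure has zero energy
  expect_equal(free_energy(x1, rna_structure(NULL, 9), p)$total, 0)
})

test_that("total is the sum of the per-loop breakdown", {
  set.seed(4)
  for (rep in 1:10) {
    y <- rand_structure(40)
    x <- emit_sequence(y, generator_config(mutation_rate = 0))
    fe <- free_energy(x, y, p)
    expect_equal(fe$total, sum(fe$breakdown$dG))
  }
})

test_that("f_T is the negated free energy and rejects non-canonical pairs", {
  y <- parse_dotbracket("(((...)))")
  x <- "GGGAAACCC"
  expect_equal(f_T(x, y, p), -free_energy(x, y, p)$total)
  expect_equal(f_T(x, rna_structure(NULL, 9), p), 0)
  # adding a stabilizing stack increases f_T
  expect_gt(f_T("GGGGAAACCCC", parse_dotbracket("((((...))))"), p),
            f_T("GGGGAAACCCC", parse_dotbracket(".(((...)))."), p))
  # A-A pair is rejected, N may never pair
  expect_error(f_T("AAGAAACAA", y, p), "non-canonical",
               class = "hybridfold_noncanonical_error")
  expect_error(f_T("NGGAAACCN", y, p),
               class = "hybridfold_noncanonical_error")
  # lenient mode zeroes only the loops touching the offending pair
  expect_equal(
    f_T("NGGAAACCN", y, p, lenient = TRUE),
    -(p$stack["GC", "GC"] + p$hairpin_init[3] +
        p$terminal_mismatch["GC", "A", "A"])
  )
})
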