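test_that("dot-bracket parsing matches bracket structure and validates", {
  y <- parse_dotbracket("(((...)))")
  expect_equal(y$pairs, rbind(c(1L, 9L), c(2L, 8L), c(3L, 7L)))
  expect_equal(y$length, 9L)

  empty <- parse_dotbracket("........")
  expect_equal(nrow(empty$pairs), 0L)
  expect_equal(empty$length, 8L)

  expect_error(parse_dotbracket("(()"), "position 1",
               class = "hybridfold_parse_error")
  expect_error(parse_dotbracket("())."), "position 3",
               class = "hybridfold_parse_error")
  expect_error(parse_dotbracket("(..)"), class = "hybridfold_hairpin_error")
})

test_that("structure invariants are enforced", {
  expect_error(rna_structure(rbind(c(1, 9), c(1, 8)), 9), "more than one")
  expect_error(rna_structure(rbind(c(1, 6), c(3, 9)), 9),
               class = "hybridfold_pseudoknot_error")
  expect_error(rna_structure(rbind(c(5, 1)), 9), "i < j")
  # lonely-pair flag
  expect_silent(rna_structure(rbind(c(1, 9)), 9))
  expect_error(rna_structure(rbind(c(1, 9)), 9, allow_lonely_pairs = FALSE),
               "lonely")
  expect_silent(rna_structure(rbind(c(1, 9), c(2, 8)), 9,
                              allow_lonely_pairs = FALSE))
})

test_that("serialization round-trips on random valid structures", {
  expect_equal(to_dotbracket(rna_structure(rbind(c(1, 5)), 6)), "(...).")
  expect_equal(to_dotbracket(rna_structure(NULL, 3)), "...")
  set.seed(71)
  for (rep in 1:25) {
    y <- rand_structure(sample(10:60, 1))
    expect_true(parse_dotbracket(to_dotbracket(y)) == y)
  }
})

test_that("loop decomposition reproduces the worked internal/stacking cases", {
  # a structure with helix 23..25 / 47..49, internal loop between (25,47)
  # and (29,43), and a hairpin inside
  L <- 60
  pairs <- rbind(c(23, 49), c(24, 48), c(25, 47), c(29, 43), c(30, 42),
                 c(31, 41))
  y <- rna_structure(pairs, L)
  loops <- decompose_loops(y)

  int <- loops[loops$kind == "internal", ]
  expect_equal(nrow(int), 1L)
  expect_equal(int$closing[[1]], c(25L, 47L))
  expect_equal(int$inner[[1]], rbind(c(29L, 43L)))
  expect_equal(int$runs[[1]], rbind(c(26L, 28L), c(44L, 46L)))

  st <- loops[loops$kind == "stacked", ]
  expect_true(any(purrr::map_lgl(st$closing, identical, c(23L, 49L))))
  first_stack <- st[purrr::map_lgl(st$closing, identical, c(23L, 49L)), ]
  expect_equal(first_stack$inner[[1]], rbind(c(24L, 48L)))
})

test_that("decomposition covers every base exactly once", {
  empty <- decompose_loops(rna_structure(NULL, 5))
  expect_equal(empty$kind, "external")
  expect_equal(empty$runs[[1]], rbind(c(1L, 5L)))

  set.seed(12)
  for (rep in 1:20) {
    L <- sample(10:70, 1)
    y <- rand_structure(L)
    loops <- decompose_loops(y)
    # one loop per closing pair plus the external loop
    expect_equal(nrow(loops), nrow(y$pairs) + 1L)
    # unpaired positions partition into the runs; paired appear in pairs
    unpaired <- sort(unlist(purrr::map(loops$runs, function(m) {
      unlist(purrr::map(seq_len(nrow(m)), function(r) m[r, 1]:m[r, 2]))
    })))
    expect_equal(unpaired, setdiff(1:L, c(y$pairs)))
  }
})

test_that("pseudoknot stripping keeps a maximum nested subset", {
  # nested input unchanged
  nested <- rbind(c(1L, 10L), c(2L, 9L))
  expect_equal(strip_pseudoknots(nested, 12, quiet = TRUE)$pairs, nested)
  # stated tie-break: lexicographically smallest retained set
  got <- strip_pseudoknots(rbind(c(1, 5), c(3, 8)), 8, quiet = TRUE)
  expect_equal(got$pairs, rbind(c(1L, 5L)))
  got2 <- strip_pseudoknots(rbind(c(1, 10), c(2, 9), c(5, 15)), 15,
                            quiet = TRUE)
  expect_equal(got2$pairs, rbind(c(1L, 10L), c(2L, 9L)))

  set.seed(9)
  for (rep in 1:20) {
    L <- 20L
    k <- sample(3:7, 1)
    idx <- sample(L, 2 * k)
    cand <- matrix(sort(idx), ncol = 2, byrow = TRUE)
    cand <- t(apply(cand, 1, sort))
    cand <- cand[cand[, 2] - cand[, 1] - 1 >= 3, , drop = FALSE]
    if (!nrow(cand)) next
    got <- strip_pseudoknots(cand, L, quiet = TRUE)
    expect_equal(nrow(got$pairs), brute_max_nested(cand))
  }
})

test_that("sequences validate and transliterate", {
  expect_equal(rna_sequence("acgt")$residues, "ACGU")
  expect_error(rna_sequence("ACXU"), "position 3",
               class = "hybridfold_residue_error")
  expect_error(rna_sequence(""), "length >= 1")
  expect_silent(rna_sequence("ACGUN"))
})
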