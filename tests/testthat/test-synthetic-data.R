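test_that("structure sampling honors density and determinism", {
  gc0 <- generator_config(pairing_density = 0)
  set.seed(1)
  expect_equal(nrow(sample_structure(50, gc0)$pairs), 0L)

  gc <- generator_config()
  set.seed(7); y1 <- sample_structure(60, gc)
  set.seed(7); y2 <- sample_structure(60, gc)
  expect_true(y1 == y2)

  # Monte-Carlo check of the generator's own density contract
  gc5 <- generator_config(pairing_density = 0.5)
  set.seed(99)
  fr <- purrr::map_dbl(1:300, function(i) {
    y <- sample_structure(60, gc5)
    2 * nrow(y$pairs) / 60
  })
  expect_gt(mean(fr), 0.35)
  expect_lt(mean(fr), 0.65)
})

test_that("sequences pair canonically at mutation 0 and follow the pair mix", {
  gc <- generator_config(mutation_rate = 0)
  set.seed(3)
  for (rep in 1:10) {
    y <- sample_structure(50, gc)
    x <- emit_sequence(y, gc)
    for (r in seq_len(nrow(y$pairs))) {
      pr <- paste0(substr(x$residues, y$pairs[r, 1], y$pairs[r, 1]),
                   substr(x$residues, y$pairs[r, 2], y$pairs[r, 2]))
      expect_true(pr %in% c("AU", "UA", "CG", "GC", "GU", "UG"))
    }
  }
  # concentrated distribution: all paired columns C/G
  gcg <- generator_config(mutation_rate = 0,
                          pair_distribution = c(CG = 1, GC = 0, AU = 0,
                                                UA = 0, GU = 0, UG = 0))
  set.seed(4)
  y <- sample_structure(50, gcg)
  x <- emit_sequence(y, gcg)
  ch <- strsplit(x$residues, "")[[1]]
  expect_true(all(ch[y$pairs[, 1]] == "C"))
  expect_true(all(ch[y$pairs[, 2]] == "G"))
})

test_that("datasets are reproducible, valid and round-trip through files", {
  gc <- generator_config(n = 6, seed = 11)
  d1 <- ht_generate_dataset(gc)
  d2 <- ht_generate_dataset(gc)
  expect_identical(d1$residues, d2$residues)
  expect_equal(nrow(d1), 6L)
  expect_equal(nrow(ht_generate_dataset(generator_config(n = 0))), 0L)

  dir1 <- withr::local_tempdir()
  ht_generate_dataset(gc, dir = dir1)
  dir2 <- withr::local_tempdir()
  ht_generate_dataset(gc, dir = dir2)
  expect_identical(readLines(file.path(dir1, "sequences.fasta")),
                   readLines(file.path(dir2, "sequences.fasta")))
  expect_identical(readLines(file.path(dir1, "synth0002.bpseq")),
                   readLines(file.path(dir2, "synth0002.bpseq")))
  # the manifest embeds output paths; its ids must match
  expect_identical(read.delim(file.path(dir1, "manifest.tsv"))$id,
                   read.delim(file.path(dir2, "manifest.tsv"))$id)
  # files parse back to the in-memory records
  fa <- read_fasta(file.path(dir1, "sequences.fasta"))
  expect_equal(fa$residues, d1$residues)
  man <- read.delim(file.path(dir1, "manifest.tsv"))
  rec <- read_structure_file(man$bpseq[3], "bpseq")
  expect_true(rec$structure[[1]] == d1$structure[[3]])
})

test_that("energy triplets carry the model's own ground-truth energies", {
  gc <- generator_config(n = 20, length_range = c(30L, 50L), seed = 21)
  tri <- generate_energy_triplets(gc)
  p <- turner_params()
  for (r in c(1, 7, 20)) {
    expect_equal(tri$dG[r],
                 free_energy(tri$residues[r], tri$structure[[r]], p)$total)
  }
  # a perfect energy predictor scores RMSE 0, rho 1
  perfect <- rmse_and_spearman(tri$dG, tri$dG)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$rho, 1)
})

test_that("shuffled predictions lose the rank correlation", {
  gc <- generator_config(n = 100, length_range = c(30L, 50L), seed = 31)
  tri <- generate_energy_triplets(gc)
  set.seed(5)
  rhos <- purrr::map_dbl(1:30, function(i) {
    rmse_and_spearman(tri$dG, sample(tri$dG))$rho
  })
  # permutation null: correlations concentrate near zero
  expect_lt(max(abs(rhos)), 0.5)
})
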