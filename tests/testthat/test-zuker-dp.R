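test_that("structure enumeration matches hand counts and the guard", {
  expect_length(enumerate_all_structures(5), 2L)   # {} and {(1,5)}
  expect_length(enumerate_all_structures(7), 8L)   # empty, 6 singles, 1 nested
  expect_length(enumerate_all_structures(4), 1L)
  # monotone in L
  n_prev <- 0L
  for (L in 4:10) {
    n <- length(enumerate_all_structures(L))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  expect_error(enumerate_all_structures(21), "guard")
})

test_that("short sequences fold to the empty structure", {
  for (x in c("G", "GC", "GGCC")) {
    res <- fold_max_score(x)
    expect_equal(nrow(res$structure$pairs), 0L)
  }
})

test_that("thermodynamic folding recovers the stable hairpin", {
  res <- fold_max_score("GGGAAACCC")
  expect_equal(to_dotbracket(res$structure), "(((...)))")
  # agrees with exhaustive enumeration
  x <- "GGGAAACCC"
  S0 <- hybridfold:::zero_scores(9)
  cands <- enumerate_all_structures(9, x = x)
  sc <- purrr::map_dbl(cands, function(y) total_score(x, y, S0))
  expect_equal(res$score, max(sc), tolerance = 1e-9)
})

test_that("DP equals the enumeration oracle across configurations", {
  set.seed(101)
  for (rep in 1:30) {
    L <- sample(5:13, 1)
    x <- rand_rna(L)
    S <- rand_scores(L)
    cfg <- hybrid_score_config(use_thermo = rep %% 2 == 0)
    opt <- fold_options(allow_lonely_pairs = rep %% 3 != 0)
    dp <- fold_max_score(x, S, cfg, opt)
    sc <- purrr::map_dbl(enumerate_all_structures(L, opt, x = x),
                         function(y) total_score(x, y, S, cfg))
    expect_equal(dp$score, max(sc), tolerance = 1e-6)
    # self-consistency of the traceback
    expect_equal(dp$score, total_score(x, dp$structure, S, cfg),
                 tolerance = 1e-9)
  }
})

test_that("loss-augmented decoding is exact and reduces to plain decoding", {
  set.seed(55)
  for (rep in 1:12) {
    L <- sample(6:12, 1)
    x <- rand_rna(L)
    S <- rand_scores(L)
    cfg <- hybrid_score_config(use_thermo = rep %% 2 == 0)
    opt <- fold_options()
    cands <- enumerate_all_structures(L, opt, x = x)
    y_ref <- cands[[sample(length(cands), 1)]]
    aug <- loss_augmented_fold(x, S, cfg, opt, y_ref)
    best <- max(purrr::map_dbl(cands, function(y) {
      total_score(x, y, S, cfg) + margin_delta(y_ref, y)
    }))
    expect_equal(aug$score, best, tolerance = 1e-6)
    # zero deltas: identical to the plain fold
    a0 <- loss_augmented_fold(x, S, cfg, opt, y_ref, 0, 0)
    p0 <- fold_max_score(x, S, cfg, opt)
    expect_equal(a0$score, p0$score)
    expect_true(a0$structure == p0$structure)
    # augmenting with the model's own prediction cannot lower the score
    expect_gte(loss_augmented_fold(x, S, cfg, opt, p0$structure)$score,
               p0$score - 1e-9)
  }
})

test_that("traceback is deterministic and prefers pairing on ties", {
  # all-zero scores without thermodynamics: every structure ties at the
  # total u-score; with u == 0 everything scores 0 and the tie-break
  # must still give a reproducible answer
  L <- 12
  x <- "GGGGAAAACCCC"
  S <- hybridfold:::zero_scores(L)
  cfg <- hybrid_score_config(use_thermo = FALSE)
  r1 <- fold_max_score(x, S, cfg)
  r2 <- fold_max_score(x, S, cfg)
  expect_true(r1$structure == r2$structure)
  expect_equal(r1$score, 0)
  # pairing preferred over not pairing on exact ties
  expect_gt(nrow(r1$structure$pairs), 0L)
})

test_that("a uniform bonus on stacking scores never removes stacked pairs", {
  set.seed(77)
  x <- rand_rna(40)
  S <- rand_scores(40)
  n_stacks <- function(S) {
    y <- fold_max_score(x, S)$structure
    loops <- decompose_loops(y)
    sum(loops$kind == "stacked")
  }
  base <- n_stacks(S)
  S2 <- S; S2$s <- S$s + 2
  expect_gte(n_stacks(S2), base)
})
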