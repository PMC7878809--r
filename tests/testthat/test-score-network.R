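cfg_small <- network_config(d = 8, N1 = 1, N2 = 1, N3 = 1, h = 6)

test_that("forward output has the contracted shape, even at L = 1", {
  w <- nn_init(cfg_small, seed = 1)
  for (x in c("G", "GGGAAACCC")) {
    S <- nn_forward(x, w)
    L <- nchar(x)
    expect_named(S, c("s", "o", "c", "u"))
    for (m in S) expect_equal(dim(m), c(L, L))
  }
})

test_that("zero-initialized output layer yields identically zero scores", {
  # nn_init() zeroes the final MLP layer: the freshly initialized hybrid
  # model is exactly the thermodynamic model
  w <- nn_init(cfg_small, seed = 2)
  S <- nn_forward("ACGUACGUACGU", w)
  expect_true(all(unlist(S) == 0))
})

test_that("evaluation mode is deterministic; training mode is not", {
  w <- nn_init(cfg_small, seed = 3)
  set.seed(1); w$w <- rnorm(length(w$w), 0, 0.1)
  x <- "GGGCAAACGCCC"
  expect_identical(nn_forward(x, w), nn_forward(x, w))
  set.seed(10); a <- nn_forward(x, w, training = TRUE)
  set.seed(11); b <- nn_forward(x, w, training = TRUE)
  expect_false(identical(a, b))
  # but reproducible under the same seed
  set.seed(10); a2 <- nn_forward(x, w, training = TRUE)
  expect_identical(a, a2)
})

test_that("parameter counts match hand arithmetic", {
  # MLP alone for d = 64, h = 32: 64*32+32 + 32*32+32 + 32*4+4 = 3268
  mlp_only <- count_parameters(network_config(d = 64, N1 = 0, N2 = 0, N3 = 0,
                                              h = 32)) -
    6 * 64  # embedding
  expect_equal(mlp_only, 3268)
  # layout table is consistent with the total
  lay <- hybridfold:::weight_layout(cfg_small)
  expect_equal(sum(lay$size), count_parameters(cfg_small))
  expect_equal(length(nn_init(cfg_small)$w), count_parameters(cfg_small))
  expect_error(network_config(d = 0))
  expect_error(network_config(d = 7))
})

test_that("analytic gradients match finite differences for every group", {
  set.seed(42)
  w <- nn_init(cfg_small, seed = 7)
  set.seed(1); w$w <- rnorm(length(w$w), 0, 0.2)
  x <- rna_sequence("GGGACGAUCC")
  codes <- hybridfold:::seq_codes(x)
  L <- x$length
  gS <- list(s = matrix(rnorm(L * L), L), o = matrix(rnorm(L * L), L),
             c = matrix(rnorm(L * L), L), u = matrix(rnorm(L * L), L))
  fobj <- function(wv) {
    ww <- w; ww$w <- wv
    S <- nn_forward(x, ww)
    sum(gS$s * S$s + gS$o * S$o + gS$c * S$c + gS$u * S$u)
  }
  fwd <- hybridfold:::nn_forward_cached(codes, w, training = FALSE)
  g <- hybridfold:::nn_backward(codes, w, fwd, gS)
  # probe a few weights from every parameter group
  lay <- hybridfold:::weight_layout(cfg_small)
  set.seed(3)
  idx <- unlist(purrr::map2(lay$offset, lay$size,
                            function(o, s) o + sample(s, min(s, 2))))
  eps <- 1e-5
  num <- purrr::map_dbl(idx, function(i) {
    wp <- w$w; wm <- w$w
    wp[i] <- wp[i] + eps; wm[i] <- wm[i] - eps
    (fobj(wp) - fobj(wm)) / (2 * eps)
  })
  rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-6)
  expect_lt(max(rel), 1e-3)
  # gradient reaches every parameter group
  grp <- purrr::map_dbl(seq_len(nrow(lay)), function(r) {
    sum(abs(g[lay$offset[r] + seq_len(lay$size[r])]))
  })
  expect_true(all(grp > 0))
})

test_that("weights serialize bit-exactly", {
  w <- nn_init(cfg_small, seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(w, f)
  expect_identical(load_model(f), w)
})

test_that("malformed inputs are rejected", {
  w <- nn_init(cfg_small, seed = 1)
  w_bad <- w; w_bad$w[5] <- NaN
  expect_error(nn_forward("ACGU", w_bad), "finite")
  w_short <- w; w_short$w <- w$w[-1]
  expect_error(nn_forward("ACGU", w_short), "match")
})
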