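# shared fixtures and small independent oracles

rand_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

rand_scores <- function(L, lo = -1, hi = 1) {
  structure(
    list(s = matrix(runif(L * L, lo, hi), L),
         o = matrix(runif(L * L, lo, hi), L),
         c = matrix(runif(L * L, lo, hi), L),
         u = matrix(runif(L * L, lo, hi), L)),
    class = "folding_scores"
  )
}

# random valid nested structure via the package generator at fixed density
rand_structure <- function(L, density = 0.5) {
  sample_structure(L, generator_config(pairing_density = density))
}

# brute-force maximum nested subset by subset enumeration (oracle for
# strip_pseudoknots; use with <= 12 candidate pairs)
brute_max_nested <- function(pairs, min_hairpin = 3L) {
  n <- nrow(pairs)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    sub <- pairs[idx, , drop = FALSE]
    ok <- TRUE
    if (nrow(sub) >= 1L) {
      if (any(sub[, 2L] - sub[, 1L] - 1L < min_hairpin)) ok <- FALSE
      if (ok && anyDuplicated(c(sub))) ok <- FALSE
      if (ok && nrow(sub) >= 2L) {
        for (a in seq_len(nrow(sub) - 1L)) {
          for (b in (a + 1L):nrow(sub)) {
            i <- sub[a, 1L]; j <- sub[a, 2L]; k <- sub[b, 1L]; l <- sub[b, 2L]
            if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
              ok <- FALSE
            }
          }
        }
      }
    }
    if (ok) best <- max(best, nrow(sub))
  }
  best
}

# cached small trained models shared by the slower suites (training them
# once keeps the whole suite inside its time budget)
.model_cache <- new.env(parent = emptyenv())

small_net <- function() {
  network_config(d = 16, N1 = 1, N2 = 1, N3 = 1, h = 8, dropout = 0.1)
}

trained_small_fit <- function() {
  if (is.null(.model_cache$fit)) {
    d <- ht_generate_dataset(generator_config(n = 200, seed = 0))
    .model_cache$fit <- ht_train(d, small_net(),
                                 training_config(epochs = 20, seed = 1))
  }
  .model_cache$fit
}
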