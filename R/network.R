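#' Network architecture configuration
#'
#' Hyperparameters of the folding-score network: a trainable embedding of
#' width `d`, `N1` residual 1D-convolution blocks (kernel sizes 5 and 3),
#' `N2` BiLSTM layers with `d/2` hidden units per direction, `N3`
#' residual 2D-convolution blocks (kernels 5x5 and 3x3) over the pairwise
#' concatenation tensor, and a shared 3-layer MLP with `h` hidden units
#' emitting the four folding scores per position pair.  Defaults follow
#' the full-scale architecture (`d = 64`, `N1 = 4`, `N2 = 2`, `N3 = 4`,
#' `h = 32`, dropout 0.5); desk-scale training uses a reduced
#' configuration such as `network_config(d = 16, N1 = 1, N2 = 1, N3 = 1,
#' h = 8)`.
#'
#' @param d Embedding/channel width (must be even).
#' @param N1,N2,N3 Block repeat counts.
#' @param h MLP hidden units.
#' @param dropout Dropout fraction used in training mode.
#' @return A `network_config` list.
#' @export
network_config <- function(d = 64L, N1 = 4L, N2 = 2L, N3 = 4L, h = 32L,
                           dropout = 0.5) {
  stopifnot(d >= 2L, d %% 2L == 0L, N1 >= 0L, N2 >= 0L, N3 >= 0L, h >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(d = as.integer(d), N1 = as.integer(N1), N2 = as.integer(N2),
                 N3 = as.integer(N3), h = as.integer(h),
                 dropout = as.numeric(dropout)),
            class = "network_config")
}

#' Number of trainable parameters
#'
#' @param cfg A [network_config].
#' @return Integer-valued count of scalar weights.
#' @export
count_parameters <- function(cfg = network_config()) {
  nn_param_count_cpp(unclass(cfg))
}

# named parameter groups in the exact order the C++ engine reads the
# flat weight vector
weight_layout <- function(cfg) {
  d <- cfg$d; H <- d %/% 2L; h <- cfg$h
  rows <- list(list("embedding", c(6L, d)))
  for (b in seq_len(cfg$N1)) {
    for (K in c(5L, 3L)) {
      p <- sprintf("conv1_%d_k%d", b, K)
      rows <- c(rows, list(
        list(paste0(p, "_W"), c(K * d, d)), list(paste0(p, "_b"), d),
        list(paste0(p, "_ln_g"), d), list(paste0(p, "_ln_b"), d)
      ))
    }
  }
  for (b in seq_len(cfg$N2)) {
    for (dir in c("fwd", "bwd")) {
      p <- sprintf("lstm_%d_%s", b, dir)
      rows <- c(rows, list(
        list(paste0(p, "_Wx"), c(4L * H, d)), list(paste0(p, "_Wh"), c(4L * H, H)),
        list(paste0(p, "_b"), 4L * H)
      ))
    }
    rows <- c(rows, list(list(sprintf("lstm_%d_ln_g", b), d),
                         list(sprintf("lstm_%d_ln_b", b), d)))
  }
  for (b in seq_len(cfg$N3)) {
    for (K in c(5L, 3L)) {
      p <- sprintf("conv2_%d_k%d", b, K)
      rows <- c(rows, list(
        list(paste0(p, "_W"), c(K * K * d, d)), list(paste0(p, "_b"), d),
        list(paste0(p, "_ln_g"), d), list(paste0(p, "_ln_b"), d)
      ))
    }
  }
  rows <- c(rows, list(
    list("mlp_W1", c(d, h)), list("mlp_b1", h),
    list("mlp_W2", c(h, h)), list("mlp_b2", h),
    list("mlp_W3", c(h, 4L)), list("mlp_b3", 4L)
  ))
  sizes <- purrr::map_int(rows, function(r) as.integer(prod(r[[2]])))
  tibble(
    name = purrr::map_chr(rows, 1L),
    dims = purrr::map(rows, 2L),
    size = sizes,
    offset = cumsum(c(0L, sizes[-length(sizes)]))
  )
}

#' Initialize network weights
#'
#' Weight matrices get Glorot-uniform initialization; biases and layer
#' normalization offsets start at zero, normalization gains at one, and
#' the LSTM forget-gate bias at one.  The final MLP layer is initialized
#' to zero, so a freshly initialized hybrid model scores structures
#' exactly like the pure thermodynamic model and training learns a
#' correction on top of it.
#'
#' @param cfg A [network_config].
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return An `nn_weights` object: the configuration plus the flat
#'   numeric weight vector.
#' @export
nn_init <- function(cfg = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- weight_layout(cfg)
  w <- numeric(sum(lay$size))
  for (r in seq_len(nrow(lay))) {
    nm <- lay$name[r]; dims <- lay$dims[[r]]; off <- lay$offset[r]
    idx <- off + seq_len(lay$size[r])
    if (grepl("_ln_g$", nm)) {
      w[idx] <- 1
    } else if (nm %in% c("mlp_W3", "mlp_b3") || grepl("_(b|ln_b)$", nm)) {
      w[idx] <- 0
      if (grepl("^lstm_.*_b$", nm) && !grepl("ln_b$", nm)) {
        H4 <- dims[[1]]; H <- H4 %/% 4L
        w[idx[(H + 1L):(2L * H)]] <- 1  # forget-gate bias
      }
    } else if (length(dims) == 2L) {
      lim <- sqrt(6 / (dims[1] + dims[2]))
      w[idx] <- runif(lay$size[r], -lim, lim)
    } else {
      w[idx] <- 0
    }
  }
  structure(list(cfg = cfg, w = w, version = 1L), class = "nn_weights")
}

#' @export
print.nn_weights <- function(x, ...) {
  cat(sprintf("<nn_weights> d=%d N1=%d N2=%d N3=%d h=%d (%s parameters)\n",
              x$cfg$d, x$cfg$N1, x$cfg$N2, x$cfg$N3, x$cfg$h,
              format(length(x$w), big.mark = ",")))
  invisible(x)
}

.as_weights <- function(model) {
  if (inherits(model, "ht_fit")) return(model$weights)
  if (inherits(model, "nn_weights")) return(model)
  abort("`model` must be an nn_weights object or an ht_train() fit")
}

#' Compute folding scores for a sequence
#'
#' Runs the network forward, producing the four L x L folding-score
#' matrices: helix stacking `s`, helix opening `o`, helix closing `c`
#' and unpaired region `u`.  Evaluation mode (`training = FALSE`) is
#' deterministic; training mode applies dropout.
#'
#' @param x An [rna_sequence] or string.
#' @param model An `nn_weights` object or [ht_train()] fit.
#' @param training Apply dropout (training mode)?
#' @return A `folding_scores` object (list of four L x L matrices).
#' @export
nn_forward <- function(x, model, training = FALSE) {
  x <- as_rna_sequence(x)
  wts <- .as_weights(model)
  out <- nn_forward_cpp(seq_codes(x), unclass(wts$cfg), wts$w, training)
  structure(out[c("s", "o", "c", "u")], class = "folding_scores")
}

# forward keeping the activation/dropout cache for a later backward pass
nn_forward_cached <- function(codes, wts, training = TRUE) {
  out <- nn_forward_cache_cpp(codes, unclass(wts$cfg), wts$w, training)
  out
}

nn_backward <- function(codes, wts, cache, gS) {
  nn_backward_cpp(codes, unclass(wts$cfg), wts$w, cache$state,
                  gS$s, gS$o, gS$c, gS$u)
}

#' Save and load model checkpoints
#'
#' Checkpoints serialize the configuration and the flat weight vector
#' (and, for fits, the optimizer state) bit-exactly.
#'
#' @param model An `nn_weights` object or `ht_fit`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()`
#'   returns the restored object.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
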