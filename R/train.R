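#' Training configuration for the max-margin objective
#'
#' Defaults follow the method's stated hyperparameters: margin weights
#' `deltaFN = 0.5` per false-negative and `deltaFP = 0.005` per
#' false-positive base pair, thermodynamic-regularization weight
#' `C1 = 0.125` and l2 weight `C2 = 0.01`.  Optimization uses Adam.
#'
#' @param deltaFN,deltaFP Margin weights (>= 0).
#' @param C1 Thermodynamic-regularization weight.
#' @param C2 l2 regularization weight (applied to the l2 *norm* once per
#'   mini-batch).
#' @param learning_rate,epochs,batch_size Adam settings.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param max_length Sequences longer than this are skipped with a
#'   warning.
#' @return A `training_config` list.
#' @export
training_config <- function(deltaFN = 0.5, deltaFP = 0.005, C1 = 0.125,
                            C2 = 0.01, learning_rate = 0.01, epochs = 20L,
                            batch_size = 4L, seed = 1L, max_length = 500L) {
  stopifnot(deltaFN >= 0, deltaFP >= 0, C1 >= 0, C2 >= 0,
            learning_rate >= 0, epochs >= 0L, batch_size >= 1L)
  structure(list(deltaFN = deltaFN, deltaFP = deltaFP, C1 = C1, C2 = C2,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 max_length = as.integer(max_length)),
            class = "training_config")
}

#' Margin between two structures
#'
#' `Delta(y_ref, y_hat) = deltaFN * |false negatives| + deltaFP *
#' |false positives|`, counting base pairs.  `Delta(y, y) = 0` and
#' `Delta >= 0` always.
#'
#' @param y_ref,y_hat Structures on the same sequence length.
#' @param deltaFN,deltaFP Margin weights.
#' @return Numeric margin value.
#' @export
margin_delta <- function(y_ref, y_hat, deltaFN = 0.5, deltaFP = 0.005) {
  if (y_ref$length != y_hat$length) abort("structures refer to different L")
  cf <- basepair_confusion(y_ref, y_hat)
  deltaFN * cf[["FN"]] + deltaFP * cf[["FP"]]
}

#' Structured hinge loss of one example
#'
#' `max over competitors of [f(x, y') + Delta(y, y')] - f(x, y)`,
#' computed exactly with [loss_augmented_fold()].  Non-negative because
#' the reference itself is a feasible competitor with zero margin; zero
#' exactly when the reference out-scores every competitor by its margin.
#'
#' @inheritParams fold_max_score
#' @param y Reference structure.
#' @param tc A [training_config] (supplies the margin weights).
#' @return Numeric loss value.
#' @export
structured_hinge <- function(x, y, S, cfg = hybrid_score_config(),
                             opt = fold_options(), tc = training_config(),
                             lenient = TRUE) {
  aug <- loss_augmented_fold(x, S, cfg, opt, y_ref = y,
                             deltaFN = tc$deltaFN, deltaFP = tc$deltaFP)
  aug$score - total_score(x, y, S, cfg, lenient = lenient)
}

#' Thermodynamic regularizer
#'
#' `C1 * (f(x, y) - f_T(x, y))^2 = C1 * f_W(x, y, S)^2`, evaluated on the
#' reference structure: it penalizes network scores that drive the
#' hybrid score away from the negated free energy, anchoring the learned
#' model to thermodynamics.
#'
#' @inheritParams structured_hinge
#' @param C1 Regularization weight.
#' @return Numeric penalty value.
#' @export
thermo_regularizer <- function(x, y, S, cfg = hybrid_score_config(),
                               C1 = 0.125) {
  C1 * f_W(x, y, S)^2
}

.l2_norm <- function(w) sqrt(sum(w * w))

#' Max-margin training objective on a batch
#'
#' Sum over the batch of structured hinge + thermodynamic
#' regularization, plus `C2 * ||lambda||_2` (the l2 norm of all weights,
#' added once per batch).  Evaluated in deterministic (no-dropout) mode.
#'
#' @param data Tibble with columns `residues` and `structure` (list of
#'   [rna_structure]).
#' @param model An `nn_weights` object or fit.
#' @param tc A [training_config].
#' @param cfg A [hybrid_score_config].
#' @param opt A [fold_options].
#' @return A list with `total` and `breakdown` (tibble with per-example
#'   hinge and thermo terms and the single l2 term).
#' @export
objective <- function(data, model, tc = training_config(),
                      cfg = hybrid_score_config(), opt = fold_options()) {
  if (nrow(data) == 0L) abort("empty batch")
  wts <- .as_weights(model)
  terms <- purrr::map(seq_len(nrow(data)), function(k) {
    x <- as_rna_sequence(data$residues[k])
    y <- data$structure[[k]]
    S <- nn_forward(x, wts)
    c(hinge = structured_hinge(x, y, S, cfg, opt, tc),
      thermo = thermo_regularizer(x, y, S, cfg, tc$C1))
  })
  bd <- dplyr::bind_rows(purrr::map(terms, as.list))
  l2 <- tc$C2 * .l2_norm(wts$w)
  list(total = sum(bd$hinge) + sum(bd$thermo) + l2,
       breakdown = dplyr::mutate(bd, l2 = c(l2, rep(0, nrow(bd) - 1L))))
}

#' Train the folding-score network with the max-margin framework
#'
#' Minimizes, over the network weights, the sum over training examples
#' of the structured hinge loss (computed exactly per example by
#' loss-augmented Zuker decoding) plus the thermodynamic regularizer
#' `C1 * f_W(x, y)^2`, plus `C2 * ||lambda||_2` per mini-batch, using
#' Adam.  The argmax structure of the hinge is treated as constant
#' during backpropagation (the standard structured-SVM subgradient).
#'
#' @param data Tibble with columns `id`, `residues`, `structure` (list
#'   column of [rna_structure]), e.g. from [ht_generate_dataset()] or
#'   assembled from [read_structure_file()] records.
#' @param net_cfg A [network_config].
#' @param tc A [training_config].
#' @param cfg A [hybrid_score_config].
#' @param opt A [fold_options].
#' @param resume An earlier `ht_fit` to continue from (same shapes).
#' @param verbose Print per-epoch objective values.
#' @return An `ht_fit` object with elements `weights`, `history` (one
#'   row per epoch: mean hinge, mean thermo, l2, mean objective per
#'   example), `optimizer` and the configurations used.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
ht_train <- function(data, net_cfg = network_config(), tc = training_config(),
                     cfg = hybrid_score_config(), opt = fold_options(),
                     resume = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  if (!all(purrr::map_lgl(data$structure, inherits, "rna_structure"))) {
    abort("every training record needs a reference rna_structure")
  }
  keep <- nchar(data$residues) <= tc$max_length
  if (!all(keep)) {
    warn(sprintf("skipping %d sequence(s) longer than %d bases",
                 sum(!keep), tc$max_length))
    data <- data[keep, , drop = FALSE]
  }
  for (k in seq_len(nrow(data))) {
    if (data$structure[[k]]$length != nchar(data$residues[k])) {
      abort(sprintf("structure/sequence length mismatch in record %d", k))
    }
  }
  n <- nrow(data)
  set.seed(tc$seed)
  if (is.null(resume)) {
    wts <- nn_init(net_cfg)
    m <- numeric(length(wts$w)); v <- numeric(length(wts$w)); step <- 0L
  } else {
    wts <- resume$weights
    m <- resume$optimizer$m; v <- resume$optimizer$v
    step <- resume$optimizer$step
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  codes_all <- purrr::map(data$residues, function(r) seq_codes(rna_sequence(r)))
  thermo_cpp <- .thermo_cpp(cfg$thermo)

  history <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    hinge_sum <- 0; thermo_sum <- 0; l2_last <- tc$C2 * .l2_norm(wts$w)
    for (batch in batches) {
      grad <- numeric(length(wts$w))
      for (k in batch) {
        codes <- codes_all[[k]]
        x <- rna_sequence(data$residues[k])
        y <- data$structure[[k]]
        L <- x$length
        fwd <- nn_forward_cached(codes, wts, training = TRUE)
        S <- structure(fwd[c("s", "o", "c", "u")], class = "folding_scores")
        bonus <- matrix(tc$deltaFP, L, L)
        if (nrow(y$pairs)) bonus[y$pairs] <- -tc$deltaFN
        res <- dp_fold_cpp(codes, S$s, S$o, S$c, S$u, bonus, cfg$use_thermo,
                           thermo_cpp, opt$min_hairpin, opt$max_internal_span,
                           opt$allow_lonely_pairs)
        y_hat <- rna_structure(res$pairs, L, opt$min_hairpin)
        aug <- res$score + tc$deltaFN * nrow(y$pairs)
        f_ref <- total_score(x, y, S, cfg, lenient = TRUE)
        hinge <- max(aug - f_ref, 0)
        fw_ref <- f_W(x, y, S)
        hinge_sum <- hinge_sum + hinge
        thermo_sum <- thermo_sum + tc$C1 * fw_ref^2
        G_hat <- score_gradient_matrices(x, y_hat)
        G_ref <- score_gradient_matrices(x, y)
        coef <- 2 * tc$C1 * fw_ref
        gS <- list(s = G_hat$s - G_ref$s + coef * G_ref$s,
                   o = G_hat$o - G_ref$o + coef * G_ref$o,
                   c = G_hat$c - G_ref$c + coef * G_ref$c,
                   u = G_hat$u - G_ref$u + coef * G_ref$u)
        grad <- grad + nn_backward(codes, wts, fwd, gS)
      }
      nw <- .l2_norm(wts$w)
      if (nw > 0) grad <- grad + tc$C2 * wts$w / nw
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * grad
      v <- beta2 * v + (1 - beta2) * grad^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      wts$w <- wts$w - tc$learning_rate * mhat / (sqrt(vhat) + eps)
      l2_last <- tc$C2 * .l2_norm(wts$w)
    }
    history[[epoch]] <- tibble(
      epoch = epoch,
      hinge = hinge_sum / n,
      thermo = thermo_sum / n,
      l2 = l2_last,
      objective = hinge_sum / n + thermo_sum / n + l2_last
    )
    if (verbose) {
      message(sprintf("epoch %d: objective %.4f (hinge %.4f, thermo %.4f, l2 %.4f)",
                      epoch, history[[epoch]]$objective, history[[epoch]]$hinge,
                      history[[epoch]]$thermo, l2_last))
    }
  }
  structure(
    list(
      weights = wts,
      history = dplyr::bind_rows(history),
      optimizer = list(m = m, v = v, step = step),
      training_config = tc, score_config = cfg, fold_options = opt,
      n_train = n
    ),
    class = "ht_fit"
  )
}

#' @export
print.ht_fit <- function(x, ...) {
  cat(sprintf("<ht_fit> %d training sequences, %d epochs, %s parameters\n",
              x$n_train, nrow(x$history), format(length(x$weights$w),
                                                 big.mark = ",")))
  if (nrow(x$history)) {
    cat(sprintf("  final mean objective: %.4f\n",
                x$history$objective[nrow(x$history)]))
  }
  invisible(x)
}

#' @export
tidy.ht_fit <- function(x, ...) x$history

#' @export
glance.ht_fit <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    epochs = nrow(x$history),
    n_parameters = length(x$weights$w),
    final_objective = if (nrow(x$history)) {
      x$history$objective[nrow(x$history)]
    } else NA_real_,
    final_hinge = if (nrow(x$history)) {
      x$history$hinge[nrow(x$history)]
    } else NA_real_
  )
}

#' @export
autoplot.ht_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("hinge", "thermo", "l2",
                                                "objective"),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss per example",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
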