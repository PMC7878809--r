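#' Base-pair confusion counts
#'
#' Exact-pair matching: a predicted pair is a true positive only when
#' both endpoints equal a reference pair's.
#'
#' @param y_ref,y_pred Structures on the same sequence length.
#' @return Named numeric vector `c(TP, FP, FN)`.
#' @export
basepair_confusion <- function(y_ref, y_pred) {
  if (y_ref$length != y_pred$length) {
    abort("structures refer to different sequence lengths")
  }
  key <- function(y) {
    if (!nrow(y$pairs)) return(character(0))
    paste(y$pairs[, 1L], y$pairs[, 2L])
  }
  a <- key(y_ref); b <- key(y_pred)
  tp <- length(intersect(a, b))
  c(TP = tp, FP = length(b) - tp, FN = length(a) - tp)
}

#' Positive predictive value, sensitivity and F-value
#'
#' `PPV = TP / (TP + FP)`, `SEN = TP / (TP + FN)`, and `F` their
#' harmonic mean `2 * SEN * PPV / (SEN + PPV)`; any 0/0 is 0 by
#' convention.
#'
#' @param TP,FP,FN Non-negative counts (vectorized).
#' @return A tibble with columns `PPV`, `SEN`, `F`.
#' @export
ppv_sen_f <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) abort("counts must be non-negative")
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  ppv <- safe_div(TP, TP + FP)
  sen <- safe_div(TP, TP + FN)
  tibble(PPV = ppv, SEN = sen, F = safe_div(2 * sen * ppv, sen + ppv))
}

#' Evaluate predicted structures against references
#'
#' Tidy evaluation over a table of (reference, prediction) structure
#' pairs.  Because the field has no single convention, the summary
#' attribute reports accuracy aggregated both ways: averaging
#' per-sequence PPV/SEN/F, and pooling TP/FP/FN counts over all records
#' before computing the ratios.
#'
#' @param df A tibble with columns `reference` and `predicted`
#'   ([rna_structure] objects, or dot-bracket strings); a `structure`
#'   list column (as produced by [ht_generate_dataset()]) is accepted in
#'   place of `reference`, so `ht_generate_dataset() |> ht_fold() |>
#'   ht_evaluate()` works directly.
#' @return The input with added columns `TP`, `FP`, `FN`, `PPV`, `SEN`,
#'   `F`; the two aggregate rows are available via
#'   `attr(result, "summary")`.
#' @export
ht_evaluate <- function(df) {
  df <- as_tibble(df)
  if (!"reference" %in% names(df) && "structure" %in% names(df)) {
    df$reference <- df$structure
  }
  as_struct <- function(z) {
    if (inherits(z, "rna_structure")) z else parse_dotbracket(z)
  }
  conf <- purrr::map(seq_len(nrow(df)), function(r) {
    basepair_confusion(as_struct(df$reference[[r]]), as_struct(df$predicted[[r]]))
  })
  cf <- dplyr::bind_rows(purrr::map(conf, as.list))
  out <- dplyr::bind_cols(df, cf, ppv_sen_f(cf$TP, cf$FP, cf$FN))
  pooled <- ppv_sen_f(sum(cf$TP), sum(cf$FP), sum(cf$FN))
  summary <- dplyr::bind_rows(
    dplyr::mutate(
      tibble(PPV = mean(out$PPV), SEN = mean(out$SEN), F = mean(out$F)),
      aggregation = "per_sequence_mean"
    ),
    dplyr::mutate(pooled, aggregation = "pooled_counts")
  )
  attr(out, "summary") <- summary
  out
}

#' Energy-prediction accuracy: RMSE and Spearman correlation
#'
#' Compares reference free energies `e` (kcal/mol) with predicted
#' energies `e_hat` (conventionally the negated folding score of the
#' predicted structure): root mean square error and Spearman's rank
#' correlation (Pearson correlation of average ranks).
#'
#' @param e,e_hat Numeric vectors of equal length.
#' @return A list with `RMSE`, `rho` and `data` (per-item tibble).
#' @export
rmse_and_spearman <- function(e, e_hat) {
  stopifnot(length(e) == length(e_hat), length(e) >= 1L)
  rmse <- sqrt(mean((e - e_hat)^2))
  if (length(e) < 2L) abort("Spearman correlation needs N >= 2")
  re <- rank(e); rh <- rank(e_hat)
  # rho is undefined when either side is constant
  rho <- if (stats::sd(re) == 0 || stats::sd(rh) == 0) NA_real_ else cor(re, rh)
  list(RMSE = rmse, rho = rho, data = tibble(e = e, e_hat = e_hat))
}
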