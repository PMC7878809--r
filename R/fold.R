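#' Folding options
#'
#' Standard Zuker-style restrictions on the structure space searched by
#' the dynamic program.
#'
#' @param min_hairpin Minimum number of unpaired bases enclosed by any
#'   pair (default 3).
#' @param max_internal_span Maximum total number of unpaired bases in an
#'   internal or bulge loop (default 30).
#' @param allow_lonely_pairs Allow helices consisting of a single pair
#'   (default `TRUE`).
#' @return A `fold_options` list.
#' @export
fold_options <- function(min_hairpin = 3L, max_internal_span = 30L,
                         allow_lonely_pairs = TRUE) {
  stopifnot(min_hairpin >= 0L, max_internal_span >= 2L)
  structure(list(min_hairpin = as.integer(min_hairpin),
                 max_internal_span = as.integer(max_internal_span),
                 allow_lonely_pairs = isTRUE(allow_lonely_pairs)),
            class = "fold_options")
}

# turner_params -> flat list the C++ engine consumes
.thermo_cpp <- function(p) {
  list(
    stack = p$stack,
    hairpin = p$hairpin_init,
    bulge = p$bulge_init,
    internal = p$internal_init,
    tm = as.numeric(p$terminal_mismatch),
    mb_a = p$multibranch[["a"]], mb_b = p$multibranch[["b"]],
    mb_c = p$multibranch[["c"]],
    au = p$terminal_au_gu, extrap = p$extrapolation
  )
}

#' Predict the maximum-score secondary structure
#'
#' Exact maximization of the hybrid score [total_score()] over all
#' pseudoknot-free structures admissible under `opt`, by Zuker-style
#' dynamic programming in O(L^3) time (internal loops capped at
#' `max_internal_span` unpaired bases).  Traceback is deterministic:
#' pairing is preferred over leaving a base unpaired, then smaller `i`,
#' then smaller `j`.
#'
#' @param x An [rna_sequence] or string.
#' @param S Folding scores for `x` (default: all-zero scores, i.e.
#'   thermodynamics-only folding).
#' @param cfg A [hybrid_score_config].
#' @param opt A [fold_options].
#' @return A list with `structure` (an [rna_structure]) and `score`; the
#'   score equals `total_score(x, structure, S, cfg)` up to floating
#'   summation order.
#' @examples
#' fold_max_score("GGGAAACCC")$structure
#' @export
fold_max_score <- function(x, S = NULL, cfg = hybrid_score_config(),
                           opt = fold_options()) {
  x <- as_rna_sequence(x)
  L <- x$length
  if (is.null(S)) S <- zero_scores(L)
  res <- dp_fold_cpp(
    seq_codes(x), S$s, S$o, S$c, S$u, matrix(0, L, L),
    cfg$use_thermo, .thermo_cpp(cfg$thermo),
    opt$min_hairpin, opt$max_internal_span, opt$allow_lonely_pairs
  )
  list(structure = rna_structure(res$pairs, L, opt$min_hairpin),
       score = res$score)
}

#' Loss-augmented decoding
#'
#' Maximizes `total_score(x, y) + Delta(y_ref, y)` over the structure
#' space, where `Delta` is the margin of [margin_delta()].  The margin is
#' folded into the DP as a per-pair adjustment (`+deltaFP` for a pair not
#' in the reference, `-deltaFN` for a reference pair, plus the constant
#' `deltaFN * |y_ref|`), so the augmented objective stays
#' loop-decomposable and the search remains exact.  With both deltas 0
#' the result equals [fold_max_score()].
#'
#' @inheritParams fold_max_score
#' @param y_ref Reference structure on `x`.
#' @param deltaFN,deltaFP Margin weights per false-negative /
#'   false-positive pair.
#' @return A list with `structure` and `score` (the augmented score
#'   `total_score + Delta`).
#' @export
loss_augmented_fold <- function(x, S = NULL, cfg = hybrid_score_config(),
                                opt = fold_options(), y_ref,
                                deltaFN = 0.5, deltaFP = 0.005) {
  x <- as_rna_sequence(x)
  L <- x$length
  stopifnot(y_ref$length == L)
  if (is.null(S)) S <- zero_scores(L)
  bonus <- matrix(deltaFP, L, L)
  n_ref <- nrow(y_ref$pairs)
  if (n_ref) bonus[y_ref$pairs] <- -deltaFN
  res <- dp_fold_cpp(
    seq_codes(x), S$s, S$o, S$c, S$u, bonus,
    cfg$use_thermo, .thermo_cpp(cfg$thermo),
    opt$min_hairpin, opt$max_internal_span, opt$allow_lonely_pairs
  )
  list(structure = rna_structure(res$pairs, L, opt$min_hairpin),
       score = res$score + deltaFN * n_ref)
}

#' Enumerate every admissible secondary structure (test oracle)
#'
#' Exhaustively generates all nested pair sets on `1..L` honoring
#' `min_hairpin` (and, when a sequence is given, the canonical-pair
#' restriction).  Intended as a brute-force oracle for small `L`; guarded
#' at `L <= 20`.
#'
#' @param L Sequence length.
#' @param opt A [fold_options].
#' @param x Optional sequence; restricts candidate pairs to canonical
#'   ones.
#' @return A list of [rna_structure] objects (always includes the empty
#'   structure).
#' @export
enumerate_all_structures <- function(L, opt = fold_options(), x = NULL) {
  if (L > 20L) abort("enumeration is guarded at L <= 20")
  codes <- if (!is.null(x)) seq_codes(as_rna_sequence(x)) else NULL
  mh <- opt$min_hairpin
  allowed <- function(i, j) {
    if (j - i - 1L < mh) return(FALSE)
    if (is.null(codes)) return(TRUE)
    a <- codes[i]; b <- codes[j]
    (a == 1L && b == 4L) || (a == 4L && b == 1L) || (a == 2L && b == 3L) ||
      (a == 3L && b == 2L) || (a == 3L && b == 4L) || (a == 4L && b == 3L)
  }
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i > j) return(list(matrix(integer(), ncol = 2L)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- enum(i, j - 1L)  # j unpaired
    for (k in seq_len(max(j - mh - 1L - i + 1L, 0L)) + i - 1L) {
      if (!allowed(k, j)) next
      left <- enum(i, k - 1L)
      inside <- enum(k + 1L, j - 1L)
      for (lf in left) {
        for (ins in inside) {
          res[[length(res) + 1L]] <- rbind(lf, c(k, j), ins)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  sets <- enum(1L, L)
  if (!opt$allow_lonely_pairs) {
    sets <- purrr::keep(sets, function(m) {
      if (!nrow(m)) return(TRUE)
      pt <- integer(L)
      pt[m[, 1L]] <- m[, 2L]; pt[m[, 2L]] <- m[, 1L]
      all(apply(m, 1L, function(pr) {
        i <- pr[1L]; j <- pr[2L]
        (i + 1L < j - 1L && pt[i + 1L] == j - 1L) ||
          (i > 1L && j < L && pt[i - 1L] == j + 1L)
      }))
    })
  }
  purrr::map(sets, rna_structure, length = L, min_hairpin = mh)
}

#' Fold a table of sequences
#'
#' Tidy batch interface over [fold_max_score()]: one predicted structure
#' per input row, with the total score and its thermodynamic / network
#' breakdown.
#'
#' @param df A tibble with columns `id` and `residues` (e.g. from
#'   [read_fasta()] or [ht_generate_dataset()]), or a path to a FASTA
#'   file.
#' @param model A trained model ([ht_train()] fit or a weights object
#'   from [nn_init()]), or `NULL` for thermodynamics-only folding.
#' @param cfg A [hybrid_score_config].
#' @param opt A [fold_options].
#' @return The input tibble with added columns `predicted` (dot-bracket
#'   string), `n_pairs`, `score`, `f_T` and `f_W`, so that a table
#'   carrying reference structures pipes directly into [ht_evaluate()].
#' @export
ht_fold <- function(df, model = NULL, cfg = hybrid_score_config(),
                    opt = fold_options()) {
  if (is.character(df) && length(df) == 1L) df <- read_fasta(df)
  df <- as_tibble(df)
  if (nrow(df) == 0L) {
    return(dplyr::bind_cols(df, tibble(
      predicted = character(), n_pairs = integer(), score = numeric(),
      f_T = numeric(), f_W = numeric()
    )))
  }
  rows <- purrr::map(seq_len(nrow(df)), function(r) {
    x <- rna_sequence(df$residues[r], id = df$id[r])
    S <- if (is.null(model)) zero_scores(x$length) else nn_forward(x, model)
    fit <- fold_max_score(x, S, cfg, opt)
    ft <- if (cfg$use_thermo) f_T(x, fit$structure, cfg$thermo) else 0
    tibble(
      predicted = to_dotbracket(fit$structure),
      n_pairs = nrow(fit$structure$pairs),
      score = fit$score, f_T = ft, f_W = fit$score - ft
    )
  })
  dplyr::bind_cols(df, dplyr::bind_rows(rows))
}
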