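#' Hybrid scoring configuration
#'
#' @param use_thermo If `TRUE` (default) the hybrid score is
#'   `f_T + f_W`; if `FALSE` the score is the network term alone (the
#'   "base model" ablation).
#' @param thermo A [turner_params] object.
#' @return A `hybrid_score_config` list.
#' @export
hybrid_score_config <- function(use_thermo = TRUE, thermo = turner_params()) {
  structure(list(use_thermo = isTRUE(use_thermo), thermo = thermo),
            class = "hybrid_score_config")
}

# which folding-score matrix entries a loop reads (coefficient 1 each).
# Unpaired runs inside hairpin/internal/bulge loops use the span entry
# u[a, b]; unpaired bases in multibranch and external loops use per-base
# diagonal entries u[t, t], which is what keeps the DP cubic.
loop_score_entries <- function(loop, L) {
  kind <- loop$kind
  cl <- loop$closing
  if (!is.null(cl) && is.list(cl)) cl <- cl[[1L]]
  inner <- loop$inner
  if (is.list(inner)) inner <- inner[[1L]]
  runs <- loop$runs
  if (is.list(runs)) runs <- runs[[1L]]

  m <- character(0); ii <- integer(0); jj <- integer(0)
  add <- function(mat, a, b) {
    m <<- c(m, mat); ii <<- c(ii, a); jj <<- c(jj, b)
  }
  open_entry <- function(k, l) add("o", max(k - 1L, 1L), min(l + 1L, L))
  per_base_u <- function() {
    for (r in seq_len(nrow(runs))) {
      for (t in seq(runs[r, 1L], runs[r, 2L])) add("u", t, t)
    }
  }

  switch(kind,
    hairpin = {
      add("c", cl[1L], cl[2L])
      if (cl[2L] - cl[1L] >= 2L) add("u", cl[1L] + 1L, cl[2L] - 1L)
    },
    stacked = add("s", cl[1L], cl[2L]),
    bulge = ,
    internal = {
      add("c", cl[1L], cl[2L])
      open_entry(inner[1L, 1L], inner[1L, 2L])
      for (r in seq_len(nrow(runs))) add("u", runs[r, 1L], runs[r, 2L])
    },
    multibranch = {
      add("c", cl[1L], cl[2L])
      for (r in seq_len(nrow(inner))) open_entry(inner[r, 1L], inner[r, 2L])
      per_base_u()
    },
    external = {
      for (r in seq_len(nrow(inner))) open_entry(inner[r, 1L], inner[r, 2L])
      per_base_u()
    },
    abort(sprintf("unknown loop kind '%s'", kind))
  )
  list(matrix = m, i = ii, j = jj)
}

#' Network folding score of a single nearest-neighbor loop
#'
#' Sums the relevant entries of the four folding-score matrices: helix
#' stacking `s` for stacked pairs, helix closing `c` for the closing pair
#' of a loop, helix opening `o` at `(k - 1, l + 1)` for each inner branch
#' `(k, l)` (clamped at the sequence ends), and unpaired-region scores
#' `u` (spans in hairpin/internal/bulge loops, per-base diagonal entries
#' in multibranch and external loops).
#'
#' @param loop One row of [decompose_loops()] output (as a list).
#' @param S A `folding_scores` object (see [nn_forward()]), or any list
#'   with L x L matrices `s`, `o`, `c`, `u`.
#' @return Numeric score.
#' @export
loop_network_score <- function(loop, S) {
  e <- loop_score_entries(loop, nrow(S$s))
  if (!length(e$matrix)) return(0)
  sum(purrr::map_dbl(seq_along(e$matrix), function(k) {
    S[[e$matrix[k]]][e$i[k], e$j[k]]
  }))
}

#' Network contribution to the hybrid score
#'
#' `f_W(x, y, S)` is the sum of [loop_network_score()] over the
#' nearest-neighbor loop decomposition of `y`.
#'
#' @param x An [rna_sequence] (or string).
#' @param y An [rna_structure].
#' @param S Folding scores for `x`.
#' @return Numeric score.
#' @export
f_W <- function(x, y, S) {
  x <- as_rna_sequence(x)
  stopifnot(y$length == x$length, nrow(S$s) == x$length)
  loops <- decompose_loops(y)
  sum(purrr::map_dbl(seq_len(nrow(loops)), function(r) {
    loop_network_score(as.list(loops[r, ]), S)
  }))
}

#' Hybrid folding score of a structure
#'
#' The score maximized by the folding engine:
#' `f(x, y) = f_T(x, y) + f_W(x, y, S)` when `use_thermo` is `TRUE`,
#' else `f_W` alone.  Both terms decompose over nearest-neighbor loops,
#' so the total is exactly loop-decomposable.
#'
#' @inheritParams f_W
#' @param cfg A [hybrid_score_config].
#' @return Numeric score.
#' @export
#' @param lenient Passed to [f_T()]: loops involving non-canonical pairs
#'   (possible in reference structures, never in predictions) contribute
#'   only their network term.
total_score <- function(x, y, S, cfg = hybrid_score_config(),
                        lenient = FALSE) {
  fw <- f_W(x, y, S)
  if (cfg$use_thermo) fw + f_T(x, y, cfg$thermo, lenient = lenient) else fw
}

# accumulate d(total network score)/dS as four L x L matrices; used for
# the subgradient of the structured hinge and the thermo regularizer
score_gradient_matrices <- function(x, y) {
  x <- as_rna_sequence(x)
  L <- x$length
  G <- list(s = matrix(0, L, L), o = matrix(0, L, L),
            c = matrix(0, L, L), u = matrix(0, L, L))
  loops <- decompose_loops(y)
  for (r in seq_len(nrow(loops))) {
    e <- loop_score_entries(as.list(loops[r, ]), L)
    for (k in seq_along(e$matrix)) {
      G[[e$matrix[k]]][e$i[k], e$j[k]] <- G[[e$matrix[k]]][e$i[k], e$j[k]] + 1
    }
  }
  G
}

# zero folding scores for thermodynamics-only folding
zero_scores <- function(L) {
  z <- matrix(0, L, L)
  structure(list(s = z, o = z, c = z, u = z), class = "folding_scores")
}
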