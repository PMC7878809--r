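#' Load the nearest-neighbor free-energy parameter table
#'
#' Parses the plain-text parameter fixture shipped with the package (or a
#' user-supplied file in the same format) into lookup tables used by
#' [free_energy()] and the folding engine.  The shipped table is a reduced
#' Turner-style set: base-pair stacking, length-indexed hairpin / bulge /
#' internal-loop initiations, terminal mismatches, an affine multibranch
#' model `a + b * branches + c * unpaired`, a terminal AU/GU helix-end
#' penalty, and a Jacobson-Stockmayer logarithmic length extrapolation.
#' Dangling ends and coaxial stacking are not modelled.
#'
#' @param path Path to a parameter file; defaults to the shipped fixture.
#' @return An object of class `turner_params`.
#' @export
turner_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "turner_reduced.txt", package = "hybridfold")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- sub("^\\[(.*)\\]$", "\\1", lines[grepl("^\\[", lines)])

  kv <- strsplit(lines[sec == 0L], "\\s+")
  scalars <- setNames(
    as.numeric(purrr::map_chr(kv, 2L)),
    purrr::map_chr(kv, 1L)
  )

  block <- function(name) {
    k <- match(name, headers)
    body <- lines[sec == k & !grepl("^\\[", lines)]
    strsplit(body, "\\s+")
  }

  pairs <- CANONICAL_PAIRS
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  for (f in block("stack")) stack[f[1L], f[2L]] <- as.numeric(f[3L])

  len_table <- function(name, max_len = 30L) {
    v <- rep(NA_real_, max_len)
    for (f in block(name)) v[as.integer(f[1L])] <- as.numeric(f[2L])
    v
  }
  bases <- c("A", "C", "G", "U")
  tm <- array(0, dim = c(6L, 4L, 4L), dimnames = list(pairs, bases, bases))
  for (f in block("terminal_mismatch")) {
    tm[f[1L], f[2L], f[3L]] <- as.numeric(f[4L])
  }

  p <- list(
    stack = stack,
    hairpin_init = len_table("hairpin_init"),
    bulge_init = len_table("bulge_init"),
    internal_init = len_table("internal_init"),
    terminal_mismatch = tm,
    multibranch = c(
      a = unname(scalars["multibranch_offset"]),
      b = unname(scalars["multibranch_branch"]),
      c = unname(scalars["multibranch_unpaired"])
    ),
    terminal_au_gu = unname(scalars["terminal_au_gu"]),
    extrapolation = unname(scalars["extrapolation"]),
    RT = unname(scalars["RT"]),
    source = path
  )
  stopifnot(
    !anyNA(p$stack),
    !anyNA(p$hairpin_init[3:30]),
    !anyNA(p$bulge_init[1:30]),
    !anyNA(p$internal_init[2:30])
  )
  class(p) <- "turner_params"
  p
}

#' @export
print.turner_params <- function(x, ...) {
  cat("<turner_params> reduced nearest-neighbor table (kcal/mol)\n")
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

# initiation with log extrapolation beyond the table maximum
.len_init <- function(tab, len, min_len, extrap) {
  len <- max(len, min_len)
  if (len <= length(tab)) return(tab[len])
  tab[length(tab)] + extrap * log(len / length(tab))
}

.pair_name <- function(x, i, j) paste0(residue_at(x, i), residue_at(x, j))

.check_canonical <- function(x, pr, lenient = FALSE) {
  nm <- .pair_name(x, pr[1L], pr[2L])
  if (!nm %in% CANONICAL_PAIRS) {
    if (lenient) return(NA_character_)
    abort(sprintf("non-canonical pair %s at (%d, %d)", nm, pr[1L], pr[2L]),
          class = "hybridfold_noncanonical_error")
  }
  nm
}

.au_gu <- function(nm, p) {
  if (nm %in% c("AU", "UA", "GU", "UG")) p$terminal_au_gu else 0
}

# terminal mismatch for closing pair nm with loop-side neighbours a (5')
# and b (3'); N neighbours contribute 0
.tm <- function(p, nm, a, b) {
  if (a == "N" || b == "N") return(0)
  p$terminal_mismatch[nm, a, b]
}

#' Free energy of a single nearest-neighbor loop
#'
#' @param loop One row of the tibble returned by [decompose_loops()] (as a
#'   list with fields `kind`, `closing`, `inner`, `runs`).
#' @param x An [rna_sequence] (or string).
#' @param p A [turner_params] object.
#' @param lenient If `TRUE`, a loop involving a non-canonical pair
#'   contributes 0 instead of raising an error.  Reference structures
#'   from real databases (and the mutation-noised synthetic generator)
#'   contain pairs outside the canonical set, which the energy model
#'   cannot score; during training their loops fall back to the network
#'   term alone.
#' @return Free energy contribution in kcal/mol.
#' @export
loop_free_energy <- function(loop, x, p, lenient = FALSE) {
  x <- as_rna_sequence(x)
  kind <- loop$kind
  cl <- loop$closing
  if (!is.null(cl) && is.list(cl)) cl <- cl[[1L]]
  inner <- loop$inner
  if (is.list(inner)) inner <- inner[[1L]]
  runs <- loop$runs
  if (is.list(runs)) runs <- runs[[1L]]
  n_unpaired <- if (nrow(runs)) sum(runs[, 2L] - runs[, 1L] + 1L) else 0L

  if (lenient) {
    all_pairs <- rbind(if (!is.null(cl)) matrix(cl, 1L) else NULL, inner)
    for (r in seq_len(nrow(all_pairs))) {
      if (is.na(.check_canonical(x, all_pairs[r, ], lenient = TRUE))) return(0)
    }
  }

  if (kind == "external") {
    e <- 0
    for (r in seq_len(nrow(inner))) {
      e <- e + .au_gu(.check_canonical(x, inner[r, ]), p)
    }
    return(e)
  }

  cnm <- .check_canonical(x, cl)
  i <- cl[1L]; j <- cl[2L]
  switch(kind,
    hairpin = {
      len <- j - i - 1L
      e <- .len_init(p$hairpin_init, len, 3L, p$extrapolation) + .au_gu(cnm, p)
      if (len >= 1L) {
        e <- e + .tm(p, cnm, residue_at(x, i + 1L), residue_at(x, j - 1L))
      }
      e
    },
    stacked = {
      inm <- .check_canonical(x, inner[1L, ])
      p$stack[cnm, inm]
    },
    bulge = {
      inm <- .check_canonical(x, inner[1L, ])
      .len_init(p$bulge_init, n_unpaired, 1L, p$extrapolation) +
        .au_gu(cnm, p) + .au_gu(inm, p)
    },
    internal = {
      k <- inner[1L, 1L]; l <- inner[1L, 2L]
      inm <- .check_canonical(x, inner[1L, ])
      .len_init(p$internal_init, n_unpaired, 2L, p$extrapolation) +
        .tm(p, cnm, residue_at(x, i + 1L), residue_at(x, j - 1L)) +
        .tm(p, .pair_name(x, l, k), residue_at(x, l + 1L), residue_at(x, k - 1L)) +
        .au_gu(cnm, p) + .au_gu(inm, p)
    },
    multibranch = {
      e <- p$multibranch[["a"]] +
        p$multibranch[["b"]] * (nrow(inner) + 1L) +
        p$multibranch[["c"]] * n_unpaired +
        .au_gu(cnm, p)
      for (r in seq_len(nrow(inner))) {
        e <- e + .au_gu(.check_canonical(x, inner[r, ]), p)
      }
      e
    },
    abort(sprintf("unknown loop kind '%s'", kind))
  )
}

#' Free energy of a secondary structure under the nearest-neighbor model
#'
#' Decomposes `y` into nearest-neighbor loops and sums their free-energy
#' contributions.  The empty structure has energy 0.
#'
#' @inheritParams loop_free_energy
#' @param y An [rna_structure] valid on `x`.
#' @return A list with `total` (kcal/mol) and `breakdown`, a tibble of
#'   per-loop terms.
#' @export
free_energy <- function(x, y, p = turner_params(), lenient = FALSE) {
  x <- as_rna_sequence(x)
  stopifnot(y$length == x$length)
  loops <- decompose_loops(y)
  dg <- purrr::map_dbl(seq_len(nrow(loops)), function(r) {
    loop_free_energy(as.list(loops[r, ]), x, p, lenient = lenient)
  })
  list(total = sum(dg), breakdown = dplyr::mutate(loops, dG = dg))
}

#' Thermodynamic contribution to the hybrid score
#'
#' `f_T(x, y) = -free_energy(x, y)`: the negated free energy, so that more
#' stable structures score higher and the term adds directly to the
#' network folding score.
#'
#' @inheritParams free_energy
#' @return Score (unitless, commensurate with -kcal/mol).
#' @export
f_T <- function(x, y, p = turner_params(), lenient = FALSE) {
  -free_energy(x, y, p, lenient = lenient)$total
}
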