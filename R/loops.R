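#' Nearest-neighbor loop decomposition
#'
#' Rewrites a secondary structure as the unique set of nearest-neighbor
#' loops of the Turner model: hairpin loops, base-pair stackings, bulge
#' loops, internal loops, multibranch loops and the external loop.  Both
#' the free energy and the network folding score of a structure are sums
#' over this decomposition, which is what makes exact Zuker-style dynamic
#' programming possible.
#'
#' @param y An [rna_structure].
#' @return A tibble with one row per loop and columns
#'   \describe{
#'     \item{kind}{one of `"hairpin"`, `"stacked"`, `"bulge"`,
#'       `"internal"`, `"multibranch"`, `"external"`}
#'     \item{closing}{list column; the closing pair `c(i, j)` or `NULL`
#'       for the external loop}
#'     \item{inner}{list column; two-column matrix of inner (branch)
#'       pairs, ordered by `i`}
#'     \item{runs}{list column; two-column matrix of inclusive unpaired
#'       spans `(a, b)`}
#'   }
#'   The external loop is always present, possibly with zero branches.
#' @examples
#' decompose_loops(parse_dotbracket("((((...)))).."))
#' @export
decompose_loops <- function(y) {
  stopifnot(inherits(y, "rna_structure"))
  L <- y$length
  pt <- pair_table(y)

  # direct children pairs and unpaired runs strictly inside (i, j);
  # i = 0, j = L + 1 scans the external level
  scan_level <- function(i, j) {
    inner <- list(); runs <- list()
    k <- i + 1L
    run_start <- NA_integer_
    while (k <= j - 1L) {
      if (pt[k] > k) {
        if (!is.na(run_start)) {
          runs[[length(runs) + 1L]] <- c(run_start, k - 1L)
          run_start <- NA_integer_
        }
        inner[[length(inner) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else {
        if (is.na(run_start)) run_start <- k
        k <- k + 1L
      }
    }
    if (!is.na(run_start)) runs[[length(runs) + 1L]] <- c(run_start, j - 1L)
    list(
      inner = if (length(inner)) do.call(rbind, inner) else matrix(integer(), ncol = 2L),
      runs = if (length(runs)) do.call(rbind, runs) else matrix(integer(), ncol = 2L)
    )
  }

  classify <- function(n_inner, n_unpaired, n_runs) {
    if (n_inner == 0L) "hairpin"
    else if (n_inner == 1L && n_unpaired == 0L) "stacked"
    else if (n_inner == 1L && n_runs == 1L) "bulge"
    else if (n_inner == 1L) "internal"
    else "multibranch"
  }

  n <- nrow(y$pairs)
  kind <- character(n + 1L)
  closing <- vector("list", n + 1L)
  inner <- vector("list", n + 1L)
  runs <- vector("list", n + 1L)
  if (n) {
    for (r in seq_len(n)) {
      i <- y$pairs[r, 1L]; j <- y$pairs[r, 2L]
      lv <- scan_level(i, j)
      un <- if (nrow(lv$runs)) sum(lv$runs[, 2L] - lv$runs[, 1L] + 1L) else 0L
      kind[r] <- classify(nrow(lv$inner), un, nrow(lv$runs))
      closing[[r]] <- c(i, j)
      inner[[r]] <- lv$inner
      runs[[r]] <- lv$runs
    }
  }
  ext <- scan_level(0L, L + 1L)
  kind[n + 1L] <- "external"
  closing[n + 1L] <- list(NULL)
  inner[[n + 1L]] <- ext$inner
  runs[[n + 1L]] <- ext$runs

  tibble(kind = kind, closing = closing, inner = inner, runs = runs)
}
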