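#' Secondary structures as nested base-pair sets
#'
#' An `rna_structure` is a pseudoknot-free (nested) set of base pairs
#' `(i, j)` with `1 <= i < j <= L` on a sequence of length `L`.  Each
#' position belongs to at most one pair, no two pairs cross, and every
#' hairpin encloses at least `min_hairpin` unpaired bases.
#'
#' @param pairs A two-column integer matrix (or empty) of pairs `(i, j)`.
#' @param length Sequence length `L` the structure refers to.
#' @param min_hairpin Minimum number of unpaired bases enclosed by a pair
#'   (default 3, the standard nearest-neighbor steric constraint).
#' @param allow_lonely_pairs If `FALSE`, isolated helices of a single pair
#'   are rejected.
#' @return An object of class `rna_structure` with fields `pairs` (ordered
#'   by `i`) and `length`.
#' @examples
#' rna_structure(rbind(c(1, 9), c(2, 8), c(3, 7)), length = 9)
#' parse_dotbracket("(((...)))")
#' @export
rna_structure <- function(pairs, length, min_hairpin = 3L,
                          allow_lonely_pairs = TRUE) {
  L <- as.integer(length)
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (!is.matrix(pairs) && base::length(pairs) == 0L)) {
    pairs <- matrix(integer(), ncol = 2L)
  }
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2L, byrow = TRUE)
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- NULL
  if (ncol(pairs) != 2L) abort("`pairs` must have two columns (i, j).")
  if (nrow(pairs)) {
    if (any(pairs[, 1L] >= pairs[, 2L])) abort("pairs must satisfy i < j")
    if (any(pairs < 1L) || any(pairs > L)) abort("pair index out of 1..L")
    idx <- c(pairs)
    if (anyDuplicated(idx)) {
      abort(sprintf("position %d occurs in more than one pair",
                    idx[duplicated(idx)][1L]))
    }
    short <- pairs[, 2L] - pairs[, 1L] - 1L < min_hairpin
    if (any(short)) {
      abort(sprintf(
        "pair (%d, %d) encloses fewer than %d unpaired bases",
        pairs[short, 1L][1L], pairs[short, 2L][1L], min_hairpin
      ), class = "hybridfold_hairpin_error")
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    cr <- .crossing_pairs(pairs)
    if (!is.null(cr)) {
      abort(sprintf("pairs (%d, %d) and (%d, %d) cross (pseudoknot)",
                    cr[1L], cr[2L], cr[3L], cr[4L]),
            class = "hybridfold_pseudoknot_error")
    }
    if (!allow_lonely_pairs) {
      pt <- integer(L)
      pt[pairs[, 1L]] <- pairs[, 2L]
      pt[pairs[, 2L]] <- pairs[, 1L]
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        inner <- i + 1L <= L && pt[i + 1L] == j - 1L && j - 1L > i + 1L
        outer <- i > 1L && j < L && pt[i - 1L] == j + 1L
        if (!inner && !outer) {
          abort(sprintf("lonely pair (%d, %d) not allowed", i, j))
        }
      }
    }
  }
  structure(list(pairs = pairs, length = L), class = "rna_structure")
}

# first crossing pair-of-pairs, or NULL (pairs ordered by i)
.crossing_pairs <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(NULL)
  open <- integer(0) # stack of row indices
  ends <- pairs[, 2L]
  k <- 1L
  # sweep: pairs sorted by i; nestedness <=> each new pair closes inside
  # the enclosing open pair
  for (r in seq_len(n)) {
    while (base::length(open) && ends[open[base::length(open)]] < pairs[r, 1L]) {
      open <- open[-base::length(open)]
    }
    if (base::length(open)) {
      top <- open[base::length(open)]
      if (pairs[r, 2L] > ends[top]) {
        return(c(pairs[top, ], pairs[r, ]))
      }
    }
    open <- c(open, r)
  }
  NULL
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> L = %d, %d pairs\n", x$length, nrow(x$pairs)))
  cat(to_dotbracket(x), "\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) to_dotbracket(x)

#' @export
`==.rna_structure` <- function(e1, e2) {
  e1$length == e2$length && nrow(e1$pairs) == nrow(e2$pairs) &&
    all(e1$pairs == e2$pairs)
}

# pairing partner vector: pt[i] = j if (i,j) or (j,i) paired, else 0
pair_table <- function(y) {
  pt <- integer(y$length)
  if (nrow(y$pairs)) {
    pt[y$pairs[, 1L]] <- y$pairs[, 2L]
    pt[y$pairs[, 2L]] <- y$pairs[, 1L]
  }
  pt
}

#' Parse and serialize dot-bracket notation
#'
#' Dot-bracket strings use `(`, `)` for paired and `.` for unpaired
#' positions; only plain parentheses are supported since the model is
#' pseudoknot-free.
#'
#' @param text A dot-bracket string.
#' @param min_hairpin Minimum hairpin size enforced on the result.
#' @return `parse_dotbracket()` returns an [rna_structure];
#'   `to_dotbracket()` returns a string.
#' @examples
#' y <- parse_dotbracket("((...))")
#' to_dotbracket(y)
#' @export
parse_dotbracket <- function(text, min_hairpin = 3L) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad)) {
    abort(sprintf("invalid character '%s' at position %d", ch[bad[1]], bad[1]),
          class = "hybridfold_parse_error")
  }
  stack <- integer(0)
  pairs <- matrix(integer(), ncol = 2L)
  out <- vector("list", sum(ch == ")"))
  k <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) {
        abort(sprintf("unmatched ')' at position %d", i),
              class = "hybridfold_parse_error")
      }
      k <- k + 1L
      out[[k]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    abort(sprintf("unclosed '(' at position %d", stack[1]),
          class = "hybridfold_parse_error")
  }
  if (k) pairs <- do.call(rbind, out)
  rna_structure(pairs, length = length(ch), min_hairpin = min_hairpin)
}

#' @rdname parse_dotbracket
#' @param y An [rna_structure].
#' @export
to_dotbracket <- function(y) {
  ch <- rep(".", y$length)
  ch[y$pairs[, 1L]] <- "("
  ch[y$pairs[, 2L]] <- ")"
  paste(ch, collapse = "")
}

#' Remove pseudoknots by keeping a maximum nested subset
#'
#' Reference structure files (BPSEQ/CT) may contain crossing base pairs;
#' the nearest-neighbor model used here is pseudoknot-free, so crossings
#' must be resolved before scoring or training.  The retained subset is a
#' maximum-cardinality nested subset of the candidate pairs, computed by
#' interval dynamic programming; ties are broken toward the
#' lexicographically smallest retained pair set.
#'
#' @param pairs Two-column matrix of candidate pairs (each position in at
#'   most one pair; pairs enclosing fewer than `min_hairpin` bases are
#'   dropped first with a warning).
#' @param length Sequence length.
#' @param min_hairpin Minimum hairpin size.
#' @param quiet Suppress the warning issued when pairs are removed.
#' @return An [rna_structure] containing the retained pairs.
#' @export
strip_pseudoknots <- function(pairs, length, min_hairpin = 3L, quiet = FALSE) {
  L <- as.integer(length)
  if (is.null(pairs) || !base::length(pairs)) {
    return(rna_structure(NULL, L, min_hairpin))
  }
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2L, byrow = TRUE)
  storage.mode(pairs) <- "integer"
  pairs <- t(apply(pairs, 1L, sort))
  if (anyDuplicated(c(pairs))) abort("a position occurs in more than one pair")
  short <- pairs[, 2L] - pairs[, 1L] - 1L < min_hairpin
  if (any(short)) {
    if (!quiet) warn(sprintf("dropped %d pair(s) enclosing < %d bases",
                             sum(short), min_hairpin))
    pairs <- pairs[!short, , drop = FALSE]
  }
  if (!nrow(pairs)) return(rna_structure(NULL, L, min_hairpin))
  keep <- max_nested_subset(pairs)
  if (nrow(keep) < nrow(pairs) && !quiet) {
    warn(sprintf("stripped %d crossing pair(s) (pseudoknot)",
                 nrow(pairs) - nrow(keep)))
  }
  rna_structure(keep, L, min_hairpin)
}

# maximum-cardinality nested subset of candidate pairs; ties broken by
# lexicographically smallest pair set (pairs compared sorted by (i, j))
max_nested_subset <- function(pairs) {
  ord <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  n <- nrow(pairs)
  memo <- new.env(parent = emptyenv())
  # candidates entirely inside [lo, hi]
  solve <- function(lo, hi) {
    key <- paste0(lo, ":", hi)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    inside <- which(pairs[, 1L] >= lo & pairs[, 2L] <= hi)
    best <- matrix(integer(), ncol = 2L)
    for (r in inside) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      cand <- rbind(c(i, j), solve(i + 1L, j - 1L), solve(j + 1L, hi))
      # pairs with i' in [lo, i) but j' > j would cross (i,j); pairs fully
      # in [lo, i-1] are compatible
      cand <- rbind(solve(lo, i - 1L), cand)
      if (better_pairset(cand, best)) best <- cand
    }
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    memo[[key]] <- best
    best
  }
  solve(min(pairs[, 1L]), max(pairs[, 2L]))
}

# TRUE if a beats b: more pairs, or equal and lexicographically smaller
better_pairset <- function(a, b) {
  if (nrow(a) != nrow(b)) return(nrow(a) > nrow(b))
  if (!nrow(a)) return(FALSE)
  a <- a[order(a[, 1L], a[, 2L]), , drop = FALSE]
  b <- b[order(b[, 1L], b[, 2L]), , drop = FALSE]
  av <- c(t(a)); bv <- c(t(b))
  d <- which(av != bv)
  if (!length(d)) return(FALSE)
  av[d[1]] < bv[d[1]]
}
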