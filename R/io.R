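#' Read RNA sequences from a FASTA file
#'
#' Records are validated against the `{A, C, G, U, N}` alphabet after
#' transliterating `T`/`t` to `U` and uppercasing, so DNA-alphabet files
#' are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `residues`, `length`, one row per
#'   record (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) {
    return(tibble(id = character(), residues = character(), length = integer()))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- purrr::map2(as.character(set), ids, rna_sequence)
  tibble(
    id = unname(ids),
    residues = unname(purrr::map_chr(seqs, "residues")),
    length = unname(purrr::map_int(seqs, "length"))
  )
}

#' Write sequences to a FASTA file
#'
#' @param df Tibble with columns `id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path) {
  set <- Biostrings::BStringSet(setNames(df$residues, df$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write secondary-structure files
#'
#' Supported formats: `bpseq` (lines `i base j`, `j = 0` for unpaired,
#' `#` comments skipped), `ct` (first line `L title`, then
#' `i base i-1 i+1 j k`), and `dotbracket` (optional `>id` header, a
#' sequence line and a structure line).  Both partner fields of a pair
#' must agree; crossing pairs are resolved through [strip_pseudoknots()]
#' with a warning, since reference databases commonly contain
#' pseudoknotted entries while the model here is pseudoknot-free.
#'
#' @param path File path.
#' @param format One of `"bpseq"`, `"ct"`, `"dotbracket"`.
#' @param min_hairpin Minimum hairpin size enforced on the structure.
#' @return A one-row tibble (a structure record) with columns `id`,
#'   `residues`, `length`, `structure` (list column holding an
#'   [rna_structure]), `source` and `format`.
#' @export
read_structure_file <- function(path, format = c("bpseq", "ct", "dotbracket"),
                                min_hairpin = 3L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  parsed <- switch(format,
    bpseq = .read_bpseq(path),
    ct = .read_ct(path),
    dotbracket = .read_dotbracket_file(path)
  )
  x <- rna_sequence(parsed$residues, id = parsed$id)
  y <- strip_pseudoknots(parsed$pairs, x$length, min_hairpin = min_hairpin)
  tibble(
    id = x$id, residues = x$residues, length = x$length,
    structure = list(y), source = path, format = format
  )
}

.read_bpseq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("empty BPSEQ file", class = "hybridfold_format_error")
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) != 3L)) {
    abort("BPSEQ lines must have 3 fields: i base j",
          class = "hybridfold_format_error")
  }
  i <- as.integer(purrr::map_chr(fields, 1L))
  base <- purrr::map_chr(fields, 2L)
  j <- as.integer(purrr::map_chr(fields, 3L))
  .pairing_from_columns(i, base, j, id = sub("\\.[^.]*$", "", basename(path)))
}

.read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) abort("empty CT file", class = "hybridfold_format_error")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  L <- suppressWarnings(as.integer(header[1L]))
  if (is.na(L)) abort("CT header must start with the length",
                      class = "hybridfold_format_error")
  id <- if (length(header) > 1L) paste(header[-1L], collapse = " ") else "ct"
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  if (length(body) != L) {
    abort(sprintf("CT file declares %d residues but has %d lines", L, length(body)),
          class = "hybridfold_format_error")
  }
  if (any(lengths(body) < 6L)) {
    abort("CT lines must have 6 fields", class = "hybridfold_format_error")
  }
  i <- as.integer(purrr::map_chr(body, 1L))
  base <- purrr::map_chr(body, 2L)
  j <- as.integer(purrr::map_chr(body, 5L))
  .pairing_from_columns(i, base, j, id = id)
}

# shared BPSEQ/CT validation: indices 1..L once each, symmetric partners
.pairing_from_columns <- function(i, base, j, id) {
  L <- length(i)
  if (anyDuplicated(i)) {
    abort(sprintf("duplicate residue index %d", i[duplicated(i)][1L]),
          class = "hybridfold_format_error")
  }
  if (!setequal(i, seq_len(L))) {
    abort("residue indices must cover 1..L", class = "hybridfold_format_error")
  }
  ord <- order(i)
  base <- base[ord]; j <- j[ord]
  if (any(is.na(j)) || any(j < 0L) || any(j > L)) {
    abort("partner index out of range", class = "hybridfold_format_error")
  }
  paired <- which(j > 0L)
  for (k in paired) {
    if (j[j[k]] != k) {
      abort(sprintf("asymmetric pairing: %d pairs %d but %d pairs %d",
                    k, j[k], j[k], j[j[k]]),
            class = "hybridfold_format_error")
    }
    if (j[k] == k) abort("a residue cannot pair with itself",
                         class = "hybridfold_format_error")
  }
  up <- paired[j[paired] > paired]
  pairs <- cbind(up, j[up])
  list(id = id, residues = paste(base, collapse = ""),
       pairs = if (nrow(pairs)) pairs else NULL)
}

.read_dotbracket_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  id <- "dotbracket"
  if (length(lines) && startsWith(lines[1L], ">")) {
    id <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) {
    abort("dot-bracket file needs a sequence line and a structure line",
          class = "hybridfold_format_error")
  }
  residues <- trimws(lines[1L]); db <- trimws(lines[2L])
  if (nchar(residues) != nchar(db)) {
    abort("sequence and structure lines differ in length",
          class = "hybridfold_format_error")
  }
  y <- parse_dotbracket(db, min_hairpin = 0L)
  list(id = id, residues = residues,
       pairs = if (nrow(y$pairs)) y$pairs else NULL)
}

#' @rdname read_structure_file
#' @param record A one-row structure record tibble (as returned by
#'   [read_structure_file()]) or a list with fields `id`, `residues`,
#'   `structure`.
#' @export
write_structure_file <- function(record, path,
                                 format = c("bpseq", "ct", "dotbracket")) {
  format <- match.arg(format)
  if (inherits(record, "data.frame")) {
    stopifnot(nrow(record) == 1L)
    record <- list(id = record$id, residues = record$residues,
                   structure = record$structure[[1L]])
  }
  y <- record$structure
  base <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  L <- length(base)
  stopifnot(y$length == L)
  pt <- pair_table(y)
  lines <- switch(format,
    bpseq = sprintf("%d %s %d", seq_len(L), base, pt),
    ct = c(
      sprintf("%d %s", L, record$id),
      sprintf("%d %s %d %d %d %d", seq_len(L), base, seq_len(L) - 1L,
              c(seq_len(L - 1L) + 1L, 0L), pt, seq_len(L))
    ),
    dotbracket = c(paste0(">", record$id), record$residues, to_dotbracket(y))
  )
  writeLines(lines, path)
  invisible(path)
}
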