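#' Synthetic dataset generator configuration
#'
#' The generator emulates desk-scale training conditions: helix-biased
#' nested structures with a target paired fraction, sequences whose
#' paired columns are drawn jointly from a canonical-pair distribution
#' (GC-biased by default, as in structured ncRNAs), and pointwise
#' mutation noise that perturbs a fraction of positions after
#' assignment.
#'
#' @param n Number of records.
#' @param length_range Inclusive `(min, max)` sequence length.
#' @param pairing_density Target fraction of paired bases.
#' @param pair_distribution Named probabilities over the six canonical
#'   pairs (must sum to 1).
#' @param mutation_rate Fraction of positions independently
#'   re-randomized after assignment (may break canonicity, emulating
#'   non-canonical pairs and misannotation in real references).
#' @param seed Integer seed; each record derives its own substream so
#'   content is independent of generation order.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 200L, length_range = c(40L, 80L),
                             pairing_density = 0.55,
                             pair_distribution = c(CG = 0.3, GC = 0.3,
                                                   AU = 0.15, UA = 0.15,
                                                   GU = 0.05, UG = 0.05),
                             mutation_rate = 0.1, seed = 0L) {
  stopifnot(n >= 0L, length(length_range) == 2L,
            length_range[1] >= 5L, length_range[1] <= length_range[2],
            pairing_density >= 0, pairing_density <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            abs(sum(pair_distribution) - 1) < 1e-8,
            all(names(pair_distribution) %in% CANONICAL_PAIRS))
  structure(list(n = as.integer(n), length_range = as.integer(length_range),
                 pairing_density = pairing_density,
                 pair_distribution = pair_distribution,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "generator_config")
}

# per-record substream: deterministic function of (seed, record index)
.record_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + k * 1009L) %% 2147483587L
}

#' Sample a nested secondary structure
#'
#' Recursive pair-or-skip construction with helix persistence: once a
#' pair is opened the next inward position stacks with high probability,
#' producing helix runs like those in real structures; the opening
#' probability is tuned so that the expected paired fraction matches
#' `pairing_density` (within about +/- 0.15).  Long unpaired stretches
#' occasionally bifurcate into two independent domains, yielding
#' multibranch and external loop diversity.
#'
#' @param L Sequence length.
#' @param gc A [generator_config].
#' @param min_hairpin Minimum hairpin size.
#' @return An [rna_structure].
#' @export
sample_structure <- function(L, gc = generator_config(), min_hairpin = 3L) {
  d <- gc$pairing_density
  stack_p <- 0.85
  pairs <- list()
  assigned <- 0L  # bases whose paired/unpaired fate is settled
  paired <- 0L
  # fraction of the not-yet-settled bases that still must pair to reach
  # the target; the opening probability tracks it, which self-corrects
  # for bases lost to hairpin/external truncation
  need <- function() (d * L - paired) / max(L - assigned, 1L)
  gen <- function(i, j, in_helix) {
    while (j - i - 1L >= min_hairpin) {
      if (in_helix && need() > 0 && runif(1) < stack_p) {
        pairs[[length(pairs) + 1L]] <<- c(i, j)
        paired <<- paired + 2L; assigned <<- assigned + 2L
        i <- i + 1L; j <- j - 1L
        next
      }
      in_helix <- FALSE
      if (runif(1) < min(1, max(0, need()))) {
        pairs[[length(pairs) + 1L]] <<- c(i, j)
        paired <<- paired + 2L; assigned <<- assigned + 2L
        i <- i + 1L; j <- j - 1L
        in_helix <- TRUE
        next
      }
      if (j - i + 1L >= 2L * (min_hairpin + 2L) + 2L && runif(1) < 0.15) {
        k <- sample((i + min_hairpin + 1L):(j - min_hairpin - 2L), 1L)
        gen(i, k, FALSE)
        i <- k + 1L
        next
      }
      if (runif(1) < 0.5) i <- i + 1L else j <- j - 1L
      assigned <<- assigned + 1L
    }
    assigned <<- assigned + max(j - i + 1L, 0L)  # truncated tail stays unpaired
  }
  if (d > 0) gen(1L, L, FALSE)
  m <- if (length(pairs)) do.call(rbind, pairs) else NULL
  rna_structure(m, L, min_hairpin)
}

#' Emit a sequence compatible with a structure
#'
#' Paired positions are drawn jointly from the configured canonical-pair
#' distribution (so every pair is canonical before mutation); unpaired
#' positions are uniform over A, C, G, U; finally each position is
#' independently re-randomized with probability `mutation_rate`.
#'
#' @param y An [rna_structure].
#' @param gc A [generator_config].
#' @return An [rna_sequence].
#' @export
emit_sequence <- function(y, gc = generator_config(), id = "synth") {
  L <- y$length
  bases <- c("A", "C", "G", "U")
  res <- sample(bases, L, replace = TRUE)
  if (nrow(y$pairs)) {
    lab <- sample(names(gc$pair_distribution), nrow(y$pairs), replace = TRUE,
                  prob = gc$pair_distribution)
    res[y$pairs[, 1L]] <- substr(lab, 1L, 1L)
    res[y$pairs[, 2L]] <- substr(lab, 2L, 2L)
  }
  if (gc$mutation_rate > 0) {
    hit <- runif(L) < gc$mutation_rate
    res[hit] <- sample(bases, sum(hit), replace = TRUE)
  }
  rna_sequence(paste(res, collapse = ""), id = id)
}

#' Generate a synthetic sequence/structure dataset
#'
#' @param gc A [generator_config].
#' @param dir Optional output directory; when given, writes a FASTA
#'   file, one BPSEQ file per record and a tab-separated manifest
#'   (`id`, `bpseq`) for training, all round-trippable through the
#'   package readers.
#' @param min_hairpin Minimum hairpin size.
#' @return A tibble with columns `id`, `residues`, `length`,
#'   `structure` (list of [rna_structure]) and `paired_fraction`.
#' @export
ht_generate_dataset <- function(gc = generator_config(), dir = NULL,
                                min_hairpin = 3L) {
  rows <- purrr::map(seq_len(gc$n), function(k) {
    set.seed(.record_seed(gc$seed, k))
    L <- sample(gc$length_range[1]:gc$length_range[2], 1L)
    y <- sample_structure(L, gc, min_hairpin)
    x <- emit_sequence(y, gc, id = sprintf("synth%04d", k))
    tibble(id = x$id, residues = x$residues, length = L,
           structure = list(y),
           paired_fraction = 2 * nrow(y$pairs) / L)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(id = character(), residues = character(), length = integer(),
           structure = list(), paired_fraction = numeric())
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(out)) write_fasta(out, file.path(dir, "sequences.fasta"))
    bp <- character(nrow(out))
    for (r in seq_len(nrow(out))) {
      bp[r] <- file.path(dir, paste0(out$id[r], ".bpseq"))
      write_structure_file(out[r, ], bp[r], "bpseq")
    }
    utils::write.table(
      data.frame(id = out$id, bpseq = bp),
      file.path(dir, "manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  out
}

#' Generate sequence/structure/energy triplets
#'
#' Mutation is forced off so that every pair is canonical and the
#' reference free energy is well defined; the energy is computed with
#' [free_energy()] under the supplied parameters, giving a ground truth
#' for RMSE / rank-correlation evaluation of energy estimates.
#'
#' @param gc A [generator_config] (its `mutation_rate` is ignored).
#' @param p A [turner_params] object.
#' @param dir Optional output directory (adds `energies.tsv`).
#' @return A tibble like [ht_generate_dataset()] with an extra `dG`
#'   column (kcal/mol).
#' @export
generate_energy_triplets <- function(gc = generator_config(), p = turner_params(),
                                     dir = NULL) {
  gc$mutation_rate <- 0
  out <- ht_generate_dataset(gc, dir = dir)
  out$dG <- purrr::map_dbl(seq_len(nrow(out)), function(r) {
    free_energy(out$residues[r], out$structure[[r]], p)$total
  })
  if (!is.null(dir) && nrow(out)) {
    utils::write.table(
      data.frame(id = out$id, dG = out$dG),
      file.path(dir, "energies.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  out
}
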