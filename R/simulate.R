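#' Simulation settings for a cleavage-sequencing experiment
#'
#' Describes a digestion-and-sequencing experiment over a set of
#' artificial RNA references: a sequence-specific endoribonuclease cuts
#' each motif occurrence 5' of the motif's middle base, fragments are
#' sequenced from their 5' ends, and read depth therefore jumps at true
#' cleavage boundaries. Defaults mirror a small bench-scale run: eight
#' references of 500-2000 nt, a UGG-specific enzyme, strong cleavage
#' signal over a thin uniform background.
#'
#' @param n_references Number of reference sequences (default 8).
#' @param length_range Integer `c(min, max)` reference length in bases
#'   (default `c(500, 2000)`).
#' @param motif Cleavage motif, DNA form (default `"TGG"`, rendered UGG).
#' @param signal_rate Mean 5'-end read count initiated at each cleaved
#'   site (default 500).
#' @param background_rate Mean 5'-end read count per non-site position
#'   (default 2).
#' @param read_length Read length in bases (default 150).
#' @param cleavage_probability Fraction of molecules cleaved at each site
#'   (default 0.9).
#' @param seed Integer seed; identical config + seed give byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_references = 8L, length_range = c(500L, 2000L),
                       motif = "TGG", signal_rate = 500,
                       background_rate = 2, read_length = 150L,
                       cleavage_probability = 0.9, seed = 1L) {
  stopifnot(n_references >= 1, length(length_range) == 2L,
            length_range[1] >= nchar(motif),
            length_range[1] <= length_range[2],
            signal_rate >= background_rate, background_rate >= 0,
            cleavage_probability >= 0, cleavage_probability <= 1,
            read_length >= 1)
  structure(list(n_references = as.integer(n_references),
                 length_range = as.integer(length_range),
                 motif = toupper(motif), signal_rate = signal_rate,
                 background_rate = background_rate,
                 read_length = as.integer(read_length),
                 cleavage_probability = cleavage_probability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run expr under a private seeded RNG stream, restoring caller state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate reference sequences with ground-truth cleavage sites
#'
#' Draws uniform-composition sequences at lengths sampled from the
#' configured range and records every occurrence of the cleavage motif as
#' a ground-truth site. The boundary convention matches the detector: for
#' a motif occurrence starting at 0-based position `s`, the cleavage
#' boundary sits 5' of the motif's second base, so the coverage-increase
#' (site) position is `s + 1` — for UGG, the first G.
#'
#' @param config A [sim_config()] object.
#' @return List with `references` (a [read_fasta()]-style data frame) and
#'   `truth` (data frame `reference_id, position, planted`; positions are
#'   0-based site indices, `planted` is `FALSE` for sites arising from
#'   the random composition).
#' @export
generate_references <- function(config = sim_config()) {
  with_seed(config$seed, {
    lens <- sample_lengths(config$length_range, config$n_references)
    residues <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1L))
    ids <- sprintf("ref%02d", seq_len(config$n_references))
    refs <- data.frame(id = ids, description = sprintf("simulated %d nt", lens),
                       residues = residues, stringsAsFactors = FALSE)
    attr(refs, "alphabet") <- "RNA"
    truth <- do.call(rbind, lapply(seq_along(ids), function(k) {
      starts <- find_motif_starts(residues[[k]], config$motif)
      data.frame(reference_id = rep(ids[[k]], length(starts)),
                 position = starts + 1L,        # 0-based site (first G)
                 planted = rep(FALSE, length(starts)),
                 stringsAsFactors = FALSE)
    }))
    list(references = refs, truth = truth)
  })
}

# Uniform draw from [min, max]; safe when min == max (no 1:n expansion).
sample_lengths <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

# 0-based start offsets of overlapping motif occurrences.
find_motif_starts <- function(residues, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(residues),
                                   fixed = TRUE)
  Biostrings::start(hits) - 1L
}

#' Simulate a cleavage-derived coverage profile
#'
#' Per-position 5'-end read counts are drawn independently:
#' `Poisson(signal_rate * cleavage_probability)` at true cleavage sites,
#' `Poisson(background_rate)` elsewhere, with position 0 additionally
#' receiving `Poisson(signal_rate)` intact-molecule 5' ends. Depth at
#' position `n` is the sum of end counts at positions `s` with
#' `s <= n < s + read_length` (reads truncate at the reference end), i.e.
#' the end-count vector convolved with a length-`read_length` box.
#'
#' @param reference_length Reference length in bases.
#' @param sites 0-based ground-truth site positions for this reference.
#' @param config A [sim_config()] object.
#' @param seed Seed for this profile (default `config$seed`).
#' @return Integer coverage vector of length `reference_length`.
#' @export
simulate_cleavage_profile <- function(reference_length, sites,
                                      config = sim_config(),
                                      seed = config$seed) {
  stopifnot(all(sites >= 0), all(sites < reference_length))
  with_seed(seed, {
    lambda <- rep(config$background_rate, reference_length)
    lambda[sites + 1L] <- config$signal_rate * config$cleavage_probability
    ends <- stats::rpois(reference_length, lambda)
    ends[1L] <- ends[1L] + stats::rpois(1L, config$signal_rate)
    csum <- cumsum(ends)
    lag <- c(rep(0L, min(config$read_length, reference_length)),
             csum)[seq_len(reference_length)]
    as.integer(csum - lag)
  })
}

#' Simulate the full digestion experiment
#'
#' Generates references plus one coverage profile per reference (seeds
#' derived deterministically from `config$seed`), optionally writing
#' `refs.fa`, `coverage.tsv` and `truth.tsv` under `out_dir`.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional output directory; created if missing.
#' @return List with `references`, `truth`, `profiles` (named list of
#'   coverage vectors) and, when written, `files`.
#' @export
simulate_cleavage_experiment <- function(config = sim_config(),
                                         out_dir = NULL) {
  gen <- generate_references(config)
  profiles <- lapply(seq_len(nrow(gen$references)), function(k) {
    id <- gen$references$id[[k]]
    sites <- gen$truth$position[gen$truth$reference_id == id]
    simulate_cleavage_profile(nchar(gen$references$residues[[k]]), sites,
                              config, seed = config$seed * 1000L + k)
  })
  names(profiles) <- gen$references$id
  out <- list(references = gen$references, truth = gen$truth,
              profiles = profiles)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(refs = file.path(out_dir, "refs.fa"),
               coverage = file.path(out_dir, "coverage.tsv"),
               truth = file.path(out_dir, "truth.tsv"))
    write_fasta(gen$references, files[["refs"]])
    write_depth_table(profiles, files[["coverage"]])
    write_results_table(gen$truth, files[["truth"]])
    out$files <- files
  }
  out
}

#' Generate a CDS set with a motif-enriched subset
#'
#' Background records are drawn with uniform base composition; a labelled
#' fraction receives extra motif insertions (overwrites at random
#' non-overlapping offsets) so that their expected motif count is about
#' `enrichment_multiplier` times the composition expectation. Used to
#' check that the burden scan recovers planted enrichment.
#'
#' @param n_records Number of CDS records (default 500).
#' @param length_range Integer `c(min, max)` CDS length (default
#'   `c(300, 3000)`).
#' @param enriched_fraction Fraction of records enriched (default 0.05).
#' @param enrichment_multiplier Target ratio of expected motif count to
#'   the composition expectation, `>= 1` (default 2).
#' @param motif Motif over `A,C,G,T` (default `"TGG"`).
#' @param seed Integer seed.
#' @return CDS data frame (`id`, `description`, `residues`, `symbol`,
#'   `product`) with logical column `enriched`.
#' @export
generate_cds_set <- function(n_records = 500L, length_range = c(300L, 3000L),
                             enriched_fraction = 0.05,
                             enrichment_multiplier = 2, motif = "TGG",
                             seed = 1L) {
  stopifnot(n_records >= 1, length_range[1] >= nchar(motif),
            length_range[1] <= length_range[2],
            enriched_fraction >= 0, enriched_fraction <= 1,
            enrichment_multiplier >= 1)
  m <- nchar(motif)
  with_seed(seed, {
    lens <- sample_lengths(length_range, n_records)
    n_enriched <- round(n_records * enriched_fraction)
    enriched <- seq_len(n_records) %in% sample(n_records, n_enriched)
    residues <- vapply(seq_len(n_records), function(k) {
      L <- lens[[k]]
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (enriched[[k]] && enrichment_multiplier > 1) {
        expect <- (L - m + 1) / 4^m
        n_extra <- max(1L, round((enrichment_multiplier - 1) * expect))
        starts <- sample(seq_len(L - m + 1L), n_extra)
        for (st in starts) {
          s[st:(st + m - 1L)] <- strsplit(motif, "", fixed = TRUE)[[1L]]
        }
      }
      paste(s, collapse = "")
    }, character(1L))
    out <- data.frame(id = sprintf("cds%04d", seq_len(n_records)),
                      description = "",
                      residues = residues,
                      symbol = "", product = "",
                      enriched = enriched, stringsAsFactors = FALSE)
    attr(out, "alphabet") <- "DNA"
    out
  })
}
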