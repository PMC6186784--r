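#' Per-site motif probability from base composition
#'
#' Probability that the motif appears at a given position of a sequence
#' under the sequence's own base composition: the product over the motif's
#' letters of that letter's frequency (for `TGG`, the T frequency times
#' the squared G frequency). Ambiguous bases (`N`) are excluded from both
#' numerator and denominator.
#'
#' @param sequence DNA residues (character scalar).
#' @param motif Motif over `A,C,G,T` (default `"TGG"`).
#' @return Probability `p` in `[0, 1]`.
#' @examples
#' composition_probability("TGG")   # (1/3) * (2/3)^2 = 4/27
#' composition_probability("ACGT")  # 1/64
#' @export
composition_probability <- function(sequence, motif = "TGG") {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  tab <- table(factor(chars[chars %in% bases], levels = bases))
  total <- sum(tab)
  if (total == 0L) stop("sequence has no A/C/G/T content", call. = FALSE)
  freq <- as.numeric(tab) / total
  names(freq) <- bases
  prod(freq[strsplit(motif, "", fixed = TRUE)[[1L]]])
}

#' Count motif occurrences in a sequence
#'
#' Overlapping exact-match scan over the coding strand; any window that
#' contains an `N` never matches.
#'
#' @param sequence DNA residues (character scalar), length at least the
#'   motif length.
#' @param motif Motif over `A,C,G,T` (default `"TGG"`).
#' @return Integer count `K`.
#' @export
count_motif <- function(sequence, motif = "TGG") {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (nchar(sequence) < nchar(motif)) {
    stop("sequence shorter than motif", call. = FALSE)
  }
  Biostrings::countPattern(motif, Biostrings::DNAString(sequence),
                           fixed = TRUE)
}

#' Upper-tail binomial probability
#'
#' `Pr(X >= K)` for `X ~ Binomial(trials_n, p)`: the probability of
#' observing at least `K` motif occurrences among `trials_n` candidate
#' positions when each carries probability `p`. Computed by direct
#' summation of the binomial mass in log space (log-sum-exp over
#' `lchoose` terms), which keeps tails down to 1e-15 accurate.
#'
#' @param trials_n Number of trials (for a triplet motif in a CDS of
#'   length `L`, `trials_n = L - 2`).
#' @param p Per-trial success probability in `[0, 1]`.
#' @param K Observed count, `0 <= K <= trials_n`.
#' @return Probability `P` in `(0, 1]` (1 whenever `K = 0`).
#' @examples
#' binomial_tail(3, 0.5, 2)  # 0.5
#' @export
binomial_tail <- function(trials_n, p, K) {
  stopifnot(length(trials_n) == 1L, length(p) == 1L, length(K) == 1L)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (K < 0 || K > trials_n) {
    stop("K must be between 0 and trials_n", call. = FALSE)
  }
  if (K == 0L) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- K:trials_n
  logterms <- lchoose(trials_n, i) + i * log(p) + (trials_n - i) * log1p(-p)
  m <- max(logterms)
  min(exp(m + log(sum(exp(logterms - m)))), 1)
}

#' Burden probability from printed table parameters
#'
#' Reconstructs the binomial upper-tail probability of a CDS from its
#' length `L`, expected motif count `E` and observed count `K` alone,
#' recovering the per-site probability as `p = E / (L - 2)`. This replays
#' published per-gene summary rows without the underlying sequences.
#'
#' @param length_L CDS length in bases (vectorised).
#' @param expected_E Expected motif count `p * (L - 2)` (vectorised).
#' @param actual_K Observed motif count (vectorised).
#' @return Numeric vector of upper-tail probabilities.
#' @examples
#' burden_from_params(1713, 23.91, 52)  # ~3.56e-07
#' @export
burden_from_params <- function(length_L, expected_E, actual_K) {
  stopifnot(all(length_L >= 3), all(expected_E >= 0),
            all(expected_E <= length_L - 2))
  mapply(function(L, E, K) binomial_tail(L - 2L, E / (L - 2), K),
         length_L, expected_E, actual_K)
}

#' Rank a CDS set by motif burden
#'
#' For every coding sequence, computes the per-site motif probability `p`
#' from its own base composition, the expected count
#' `E = p * (L - m + 1)` (`L - 2` for a triplet), the observed overlapping
#' count `K`, and the binomial upper-tail probability
#' `P = Pr(count >= K)`. Small `P` flags transcripts carrying many more
#' motifs than their composition predicts — the predicted prime cleavage
#' targets. Rows are ranked by `P` ascending (ties: `K` descending, then
#' id ascending).
#'
#' @param records Data frame with columns `id` and `residues` (optionally
#'   `symbol`, `product`), e.g. from [read_cds_fasta()].
#' @param motif Motif over `A,C,G,T` (default `"TGG"`).
#' @return Data frame with columns `id, symbol, product, length_L, p,
#'   expected_E, actual_K, P, rank`, sorted by rank.
#' @export
scan_cds_set <- function(records, motif = "TGG") {
  if (nrow(records) == 0L) stop("empty CDS set", call. = FALSE)
  m <- nchar(motif)
  L <- nchar(records$residues)
  trials <- L - m + 1L
  p <- vapply(records$residues, composition_probability, numeric(1L),
              motif = motif, USE.NAMES = FALSE)
  K <- vapply(records$residues, count_motif, integer(1L), motif = motif,
              USE.NAMES = FALSE)
  P <- vapply(seq_along(L), function(k) binomial_tail(trials[k], p[k], K[k]),
              numeric(1L))
  out <- data.frame(id = records$id,
                    symbol = records$symbol %||% rep("", nrow(records)),
                    product = records$product %||% rep("", nrow(records)),
                    length_L = L, p = p, expected_E = p * trials,
                    actual_K = K, P = P, stringsAsFactors = FALSE)
  out <- out[order(out$P, -out$actual_K, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Replay a burden table from printed parameters
#'
#' Applies [burden_from_params()] to a parameter table (columns `id`,
#' `length`, `expected_E`, `actual_K`, optionally `symbol`, `product`)
#' and ranks the rows exactly as [scan_cds_set()] does.
#'
#' @param params Data frame of printed per-CDS parameters.
#' @return Data frame with columns `id, symbol, length_L, expected_E,
#'   actual_K, P, rank`, sorted by rank.
#' @export
burden_from_table <- function(params) {
  need <- c("id", "length", "expected_E", "actual_K")
  if (!all(need %in% names(params))) {
    stop("parameter table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  P <- burden_from_params(params$length, params$expected_E, params$actual_K)
  out <- data.frame(id = params$id,
                    symbol = params$symbol %||% rep("", nrow(params)),
                    length_L = params$length, expected_E = params$expected_E,
                    actual_K = params$actual_K, P = P,
                    stringsAsFactors = FALSE)
  out <- out[order(out$P, -out$actual_K, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fraction of CDS containing the motif at least once
#'
#' @param records CDS data frame (columns `id`, `residues`).
#' @param motif Motif over `A,C,G,T` (default `"TGG"`).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_with_motif <- function(records, motif = "TGG") {
  if (nrow(records) == 0L) stop("empty CDS set", call. = FALSE)
  counts <- vapply(records$residues, count_motif, integer(1L), motif = motif,
                   USE.NAMES = FALSE)
  mean(counts >= 1L)
}

#' Read a CDS FASTA with optional annotation key-values
#'
#' Like [read_fasta()], but additionally parses `symbol=` and `product=`
#' key-values out of each record's description line.
#'
#' @param path Path to a CDS FASTA file.
#' @return [read_fasta()] data frame with added `symbol` and `product`
#'   columns (empty string where absent).
#' @export
read_cds_fasta <- function(path) {
  recs <- read_fasta(path, alphabet = "DNA")
  pick <- function(desc, key) {
    m <- regmatches(desc, regexec(paste0(key, "=(\\S+)"), desc))
    vapply(m, function(x) if (length(x) == 2L) gsub("_", " ", x[[2L]]) else "",
           character(1L))
  }
  recs$symbol <- pick(recs$description, "symbol")
  recs$product <- pick(recs$description, "product")
  recs
}
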