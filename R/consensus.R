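#' Nucleotide frequency matrix from aligned windows
#'
#' Tallies base counts per column over a set of equal-width windows
#' aligned on the cleavage boundary. `N` characters (boundary padding)
#' are skipped and deducted from the effective count of their column, so
#' column frequencies are always over observed bases only.
#'
#' @param windows Character vector of equal-width windows over
#'   `A,C,G,T,N`, or a candidate data frame carrying a `window` column.
#' @return A list of class `freq_matrix`: `width`; `counts`, a
#'   `4 x width` integer matrix with rows `A,C,G,T`; `n_effective`,
#'   per-column totals excluding `N`; `labels`, integer positions
#'   `-flank .. +flank` with the boundary nucleotide at label 0.
#' @export
build_frequency_matrix <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L) stop("no windows to align", call. = FALSE)
  widths <- nchar(windows)
  if (length(unique(widths)) != 1L) {
    stop("windows have unequal widths", call. = FALSE)
  }
  width <- widths[[1L]]
  mat <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(windows), ncol = width, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(width), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    as.integer(tab)
  }, integer(4L))
  rownames(counts) <- bases
  flank <- (width - 1L) %/% 2L
  structure(list(width = width, counts = counts,
                 n_effective = colSums(counts),
                 labels = seq_len(width) - flank - 1L),
            class = "freq_matrix")
}

#' Per-column information content in bits
#'
#' For each column, `IC = 2 - H` where `H` is the Shannon entropy (base 2)
#' of the column's base frequencies; 2 bits marks a perfectly conserved
#' position, 0 a uniform one. Columns with no observed bases get IC 0.
#'
#' @param matrix A [build_frequency_matrix()] object.
#' @param small_sample_correction Subtract the small-sample term
#'   `3 / (2 ln 2 * n_effective)` (floored at 0), as sequence-logo tools
#'   do. Off by default; with ~50 windows the term is minor.
#' @return Numeric vector of per-column IC values in `[0, 2]`.
#' @export
information_content <- function(matrix, small_sample_correction = FALSE) {
  ic <- vapply(seq_len(matrix$width), function(j) {
    n <- matrix$n_effective[[j]]
    if (n == 0L) return(0)
    f <- matrix$counts[, j] / n
    f <- f[f > 0]
    h <- -sum(f * log2(f))
    val <- 2 - h
    if (small_sample_correction) val <- val - 3 / (2 * log(2) * n)
    min(max(val, 0), 2)
  }, numeric(1L))
  unname(ic)
}

#' Call the consensus cleavage motif
#'
#' A column is called as base `b` when `b`'s frequency reaches
#' `min_frequency` and the column's information content reaches `min_ic`;
#' all other columns render as `N`. The cleavage boundary sits 5' of
#' label 0 (`cut_offset = 0`): for a UGG-specific enzyme the motif spans
#' labels -1..+1 and cleavage falls between the U and the first G.
#'
#' @param matrix A [build_frequency_matrix()] object.
#' @param min_frequency Minimum base frequency for a call (default 0.5).
#' @param min_ic Minimum column IC in bits (default 1.0).
#' @param alphabet `"DNA"` or `"RNA"`; RNA renders `T` as `U`.
#' @param small_sample_correction Passed to [information_content()].
#' @return A list of class `consensus_call`: `consensus` (string over
#'   `A,C,G,T/U,N`), `called_span` (integer `c(from, to)` labels of the
#'   maximal run of called positions, or `NULL` when nothing is called),
#'   `cut_offset` (always 0), `ic` (per-column bits).
#' @export
call_consensus <- function(matrix, min_frequency = 0.5, min_ic = 1.0,
                           alphabet = c("DNA", "RNA"),
                           small_sample_correction = FALSE) {
  alphabet <- match.arg(alphabet)
  ic <- information_content(matrix, small_sample_correction)
  calls <- vapply(seq_len(matrix$width), function(j) {
    n <- matrix$n_effective[[j]]
    if (n == 0L || ic[[j]] < min_ic) return("N")
    f <- matrix$counts[, j] / n
    top <- which.max(f)
    if (f[[top]] >= min_frequency) rownames(matrix$counts)[[top]] else "N"
  }, character(1L))
  called <- calls != "N"
  span <- NULL
  if (any(called)) {
    runs <- rle(called)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    span <- c(matrix$labels[starts[best]], matrix$labels[ends[best]])
  }
  consensus <- paste(calls, collapse = "")
  if (alphabet == "RNA") consensus <- chartr("T", "U", consensus)
  structure(list(consensus = consensus, called_span = span, cut_offset = 0L,
                 ic = ic),
            class = "consensus_call")
}

#' Sequence-logo table
#'
#' Flat per-column summary of a frequency matrix: base counts, effective
#' count, information content, and the consensus call — the numeric
#' contract behind a sequence-logo figure.
#'
#' @param matrix A [build_frequency_matrix()] object.
#' @param min_frequency,min_ic,alphabet,small_sample_correction Passed to
#'   [call_consensus()].
#' @return Data frame with columns
#'   `label, A, C, G, T, n_eff, IC_bits, call`.
#' @export
logo_table <- function(matrix, min_frequency = 0.5, min_ic = 1.0,
                       alphabet = c("DNA", "RNA"),
                       small_sample_correction = FALSE) {
  alphabet <- match.arg(alphabet)
  call <- call_consensus(matrix, min_frequency, min_ic, alphabet,
                         small_sample_correction)
  data.frame(label = matrix$labels,
             A = matrix$counts["A", ], C = matrix$counts["C", ],
             G = matrix$counts["G", ], T = matrix$counts["T", ],
             n_eff = as.integer(matrix$n_effective),
             IC_bits = call$ic,
             call = strsplit(call$consensus, "")[[1L]],
             stringsAsFactors = FALSE)
}
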