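#' Detection parameters for cleavage-site mapping
#'
#' Bundles the tunables of the coverage-based cleavage-site detector:
#' the minimum raw coverage a boundary must carry, how many top-ranked
#' boundaries to keep across all references, the half-width of the
#' sequence window extracted around each boundary, and the pseudo-count
#' substituted for zero coverage so every RCI ratio is finite.
#'
#' @param min_coverage Minimum raw coverage (default 100) required at the
#'   position tested by `coverage_filter` for a boundary to be eligible.
#' @param top_k Number of top boundaries retained across all references
#'   (default 50).
#' @param flank Half-window, in bases, extracted around each boundary
#'   (default 5, giving 11-base windows).
#' @param pseudo_count Positive value substituted for zero coverage
#'   (default 1).
#' @param coverage_filter Which position the `min_coverage` filter applies
#'   to: the downstream coverage-increase position (`"down"`, the default),
#'   the upstream position (`"up"`), or both (`"both"`). Upstream of a true
#'   cleavage site coverage is legitimately low, so filtering on the
#'   retained downstream position is the default.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(min_coverage = 100L, top_k = 50L, flank = 5L,
                             pseudo_count = 1,
                             coverage_filter = c("down", "up", "both")) {
  coverage_filter <- match.arg(coverage_filter)
  stopifnot(min_coverage >= 1, top_k >= 1, flank >= 0, pseudo_count > 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 top_k = as.integer(top_k), flank = as.integer(flank),
                 pseudo_count = pseudo_count,
                 coverage_filter = coverage_filter),
            class = "detection_params")
}

#' Relative coverage increase along one reference
#'
#' For each internal boundary the relative coverage increase (RCI) is the
#' coverage at the downstream position divided by the coverage at the
#' upstream position; a spike marks a fragment 5' boundary created by
#' endoribonuclease cleavage. Zero coverage on either side is replaced by
#' `params$pseudo_count` so the ratio is always defined and positive.
#'
#' @param coverage Non-negative integer vector of per-position coverage.
#' @param params A [detection_params()] object.
#' @return A list of class `rci_track` with `values` (RCI for 0-based
#'   boundary positions `1 .. length-1`; `values[i]` belongs to downstream
#'   position `i`) and `eligible` (parallel logical vector after the
#'   minimum-coverage filter).
#' @export
compute_rci <- function(coverage, params = detection_params()) {
  if (length(coverage) < 2L) {
    stop("coverage profile must have at least 2 positions", call. = FALSE)
  }
  if (any(coverage < 0)) stop("coverage must be non-negative", call. = FALSE)
  eff <- ifelse(coverage > 0, coverage, params$pseudo_count)
  len <- length(coverage)
  values <- eff[-1L] / eff[-len]
  up <- coverage[-len]
  down <- coverage[-1L]
  eligible <- switch(params$coverage_filter,
    down = down >= params$min_coverage,
    up   = up >= params$min_coverage,
    both = down >= params$min_coverage & up >= params$min_coverage)
  structure(list(values = values, eligible = eligible), class = "rci_track")
}

#' Select the top cleavage-boundary candidates across references
#'
#' Pools eligible boundaries from all references and keeps the
#' `params$top_k` largest RCI values. Only genuine coverage increases
#' (RCI > 1) qualify — a flat or falling boundary marks no fragment 5'
#' end, so a step profile yields exactly one candidate, at the step.
#' Ordering is fully deterministic:
#' RCI descending, then downstream coverage descending, then reference id
#' ascending, then position ascending.
#'
#' @param tracks Named list of `rci_track` objects (one per reference).
#' @param profiles Named list of coverage vectors matching `tracks`.
#' @param params A [detection_params()] object.
#' @return A data frame with columns `reference_id`, `position` (0-based
#'   index of the downstream coverage-increase nucleotide; the cleavage
#'   boundary lies 5' of it), `cov_up`, `cov_down`, `rci`; at most
#'   `params$top_k` rows, ranked as above.
#' @export
select_candidates <- function(tracks, profiles, params = detection_params()) {
  ids <- names(tracks)
  if (!setequal(ids, names(profiles))) {
    stop("tracks and profiles must cover the same references", call. = FALSE)
  }
  per_ref <- lapply(ids, function(id) {
    tr <- tracks[[id]]
    cov <- profiles[[id]]
    keep <- which(tr$eligible & tr$values > 1)
    data.frame(reference_id = rep(id, length(keep)),
               position = keep,                       # 0-based downstream idx
               cov_up = cov[keep], cov_down = cov[keep + 1L],
               rci = tr$values[keep], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_ref)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(reference_id = character(), position = integer(),
                      cov_up = integer(), cov_down = integer(),
                      rci = numeric(), stringsAsFactors = FALSE))
  }
  ord <- order(-all$rci, -all$cov_down, all$reference_id, all$position)
  out <- all[ord, , drop = FALSE][seq_len(min(params$top_k, nrow(all))), ,
                                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract aligned sequence windows around candidate boundaries
#'
#' Cuts the `2*flank + 1` bases centred on each candidate's downstream
#' position out of its reference. Positions falling outside the reference
#' are filled with `N` (and flagged `padded`) so the candidate count is
#' preserved; `N`s are excluded downstream from frequency counts. Window
#' index `flank + 1` (the centre) corresponds to motif position 0, the
#' coverage-increase nucleotide.
#'
#' @param candidates Candidate data frame from [select_candidates()].
#' @param references Reference sequences ([read_fasta()] data frame).
#' @param params A [detection_params()] object.
#' @return `candidates` with added columns `window` and `padded`, order
#'   preserved.
#' @export
extract_windows <- function(candidates, references,
                            params = detection_params()) {
  res <- stats::setNames(references$residues, references$id)
  missing <- setdiff(unique(candidates$reference_id), names(res))
  if (length(missing)) {
    stop("candidate references missing from sequence set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fl <- params$flank
  win <- character(nrow(candidates))
  padded <- logical(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    seqres <- res[[candidates$reference_id[k]]]
    len <- nchar(seqres)
    centre <- candidates$position[k] + 1L          # 1-based
    from <- centre - fl
    to <- centre + fl
    left_pad <- max(0L, 1L - from)
    right_pad <- max(0L, to - len)
    core <- substr(seqres, max(1L, from), min(len, to))
    win[k] <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
    padded[k] <- left_pad > 0L || right_pad > 0L
  }
  candidates$window <- win
  candidates$padded <- padded
  candidates
}

#' One-call cleavage-site detection
#'
#' Convenience wrapper: computes RCI tracks per reference, pools and ranks
#' eligible boundaries, and extracts the aligned windows.
#'
#' @param references Reference sequences ([read_fasta()] data frame).
#' @param profiles Named list of coverage vectors, as from
#'   [read_depth_table()].
#' @param params A [detection_params()] object.
#' @return Candidate data frame with windows (see [extract_windows()]).
#' @export
detect_cleavage_sites <- function(references, profiles,
                                  params = detection_params()) {
  profiles <- profiles[references$id]
  tracks <- lapply(profiles, compute_rci, params = params)
  cand <- select_candidates(tracks, profiles, params)
  extract_windows(cand, references, params)
}
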