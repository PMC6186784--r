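#' Read a FASTA file of nucleotide sequences
#'
#' Reads a (possibly multi-record) FASTA file into a data frame of
#' normalised nucleotide sequences. Residues are stored in DNA form:
#' `U` is accepted on input and mapped to `T`; the requested display
#' alphabet is recorded as an attribute and used again by [write_fasta()].
#'
#' @param path Path to a FASTA file.
#' @param alphabet Display alphabet, `"DNA"` or `"RNA"`. Controls how the
#'   sequences are rendered on output only; storage is always DNA.
#' @return A data frame with columns `id`, `description`, `residues`
#'   (upper-case over `A,C,G,T,N`), carrying attribute `alphabet`.
#'   Record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 test", "AUGGC"), fa)
#' read_fasta(fa, alphabet = "RNA")
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  residues <- toupper(as.character(set))
  for (k in seq_along(residues)) {
    bad <- regexpr("[^ACGTUN]", residues[[k]])
    if (bad > 0L) {
      stop(sprintf("illegal residue '%s' in record '%s' at offset %d",
                   substr(residues[[k]], bad, bad), ids[[k]], bad),
           call. = FALSE)
    }
    if (nchar(residues[[k]]) == 0L) {
      stop("empty sequence in record '", ids[[k]], "'", call. = FALSE)
    }
  }
  out <- data.frame(id = unname(ids), description = unname(desc),
                    residues = chartr("U", "T", unname(residues)),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequences to FASTA
#'
#' Renders sequences in their display alphabet (`T` is rewritten to `U`
#' when the alphabet is RNA) and writes standard multi-record FASTA.
#'
#' @param seqs Data frame as returned by [read_fasta()] (columns `id`,
#'   `residues`, optionally `description`).
#' @param path Output path.
#' @param alphabet Optional override of the `alphabet` attribute of `seqs`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = NULL) {
  alphabet <- alphabet %||% attr(seqs, "alphabet") %||% "DNA"
  res <- seqs$residues
  if (identical(alphabet, "RNA")) res <- chartr("T", "U", res)
  headers <- seqs$id
  if (!is.null(seqs$description)) {
    has_desc <- !is.na(seqs$description) & nzchar(seqs$description)
    headers[has_desc] <- paste(seqs$id[has_desc], seqs$description[has_desc])
  }
  set <- Biostrings::BStringSet(res)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sparse per-position coverage table
#'
#' The coverage TSV has columns `reference_id`, `position` (0-based) and
#' `coverage`; positions absent from the table default to coverage 0, so
#' simulator output stays small. One full-length profile is returned per
#' reference sequence.
#'
#' @param path Path to the coverage TSV.
#' @param references Reference sequences ([read_fasta()] data frame); every
#'   `reference_id` in the table must match one of their ids, and every
#'   position must lie inside the reference.
#' @return A named list of non-negative integer vectors, one per reference,
#'   each of length equal to the reference length.
#' @export
read_depth_table <- function(path, references) {
  if (!file.exists(path)) stop("coverage table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reference_id", "position", "coverage")
  if (!all(need %in% names(tab))) {
    stop("coverage table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(tab$reference_id), references$id)
  if (length(unknown)) {
    stop("coverage table references unknown ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(tab$coverage < 0)) stop("negative coverage values", call. = FALSE)
  lens <- stats::setNames(nchar(references$residues), references$id)
  profiles <- lapply(references$id, function(id) {
    rows <- tab[tab$reference_id == id, , drop = FALSE]
    len <- lens[[id]]
    if (nrow(rows) && (any(rows$position < 0) || any(rows$position >= len))) {
      stop("position outside reference '", id, "' (length ", len, ")",
           call. = FALSE)
    }
    prof <- integer(len)
    prof[rows$position + 1L] <- as.integer(rows$coverage)
    prof
  })
  stats::setNames(profiles, references$id)
}

#' Write coverage profiles as a sparse TSV
#'
#' Inverse of [read_depth_table()]: only non-zero positions are written.
#'
#' @param profiles Named list of integer coverage vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    nz <- which(profiles[[id]] != 0L)
    data.frame(reference_id = rep(id, length(nz)), position = nz - 1L,
               coverage = profiles[[id]][nz], stringsAsFactors = FALSE)
  })
  write_results_table(do.call(rbind, c(rows, list(
    data.frame(reference_id = character(), position = integer(),
               coverage = integer())))), path)
}

#' Write a stage result table as TSV
#'
#' Writes any tabular stage output with a header and stable column order.
#' Probability columns (`p`, `P` by default) are rendered in scientific
#' notation with three significant digits (`3.56E-07`); other non-integer
#' numeric columns are written at full precision so written tables can be
#' read back without loss.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param prob_cols Column names to format as probabilities.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path,
                                prob_cols = intersect(c("p", "P"), names(rows))) {
  out <- rows
  for (nm in names(out)) {
    col <- out[[nm]]
    if (!is.numeric(col)) next
    if (nm %in% prob_cols) {
      out[[nm]] <- sprintf("%.2E", col)
    } else if (!is.integer(col) && any(col != round(col), na.rm = TRUE)) {
      out[[nm]] <- sprintf("%.17g", col)
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
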