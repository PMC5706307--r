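# TSV readers/writers for the small tables the toolkit exchanges:
# bin memberships, marker hits, and generic reports.

#' Read a bin assignment table
#'
#' Two-column TSV (`contig_id`, `bin_id`; header optional, detected). Each
#' contig belongs to at most one bin.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `contig_id`, `bin_id`.
#' @export
read_bins <- function(path) {
  tab <- read_two_col(path, c("contig_id", "bin_id"))
  as_bins(tab)
}

#' Validate a bin assignment data frame
#'
#' @param x Data frame with columns `contig_id`, `bin_id`.
#' @return A validated tibble.
#' @export
as_bins <- function(x) {
  stopifnot(all(c("contig_id", "bin_id") %in% names(x)))
  out <- tibble::tibble(contig_id = as.character(x$contig_id),
                        bin_id = as.character(x$bin_id))
  dup <- unique(out$contig_id[duplicated(out$contig_id)])
  if (length(dup) > 0L) {
    abort_validation(paste0("contig(s) assigned to more than one bin: ",
                            paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (any(is.na(out$bin_id) | out$bin_id == "")) {
    abort_validation("bin_id must be non-empty")
  }
  out
}

#' Read a marker-hit table
#'
#' Three-column TSV (`bin_id`, `marker_id`, `copy_count`; header optional).
#' One row per (bin, marker) with the detected copy number; produced in
#' practice by a marker-gene annotator and in tests by the simulator.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `bin_id`, `marker_id`, `copy_count`.
#' @export
read_marker_hits <- function(path) {
  tab <- suppressWarnings(
    readr::read_tsv(path, col_types = "cci", progress = FALSE,
                    col_names = c("bin_id", "marker_id", "copy_count"))
  )
  if (nrow(tab) > 0L && is.na(tab$copy_count[1L]) &&
      identical(tolower(tab$bin_id[1L]), "bin_id")) {
    tab <- tab[-1L, ]
    tab$copy_count <- as.integer(tab$copy_count)
  }
  as_marker_hits(tab)
}

#' Validate a marker-hit data frame
#'
#' @param x Data frame with columns `bin_id`, `marker_id`, `copy_count`.
#' @return A validated tibble.
#' @export
as_marker_hits <- function(x) {
  stopifnot(all(c("bin_id", "marker_id", "copy_count") %in% names(x)))
  out <- tibble::tibble(bin_id = as.character(x$bin_id),
                        marker_id = as.character(x$marker_id),
                        copy_count = as.integer(x$copy_count))
  if (any(is.na(out$copy_count) | out$copy_count < 1L)) {
    abort_validation("copy_count must be an integer >= 1")
  }
  key <- paste(out$bin_id, out$marker_id)
  if (anyDuplicated(key)) {
    abort_validation("duplicate (bin_id, marker_id) rows in marker hits")
  }
  out
}

#' The universal bacterial single-copy marker set
#'
#' A set of 104 conserved bacterial marker genes underlies the completeness
#' and contamination metrics. The identifiers here are opaque placeholders
#' (`BM001` ... `BM104`); any annotator-specific ids can be supplied instead
#' via the `marker_ids` argument of the downstream functions.
#'
#' @param m Number of markers (default 104).
#' @return Character vector of marker identifiers.
#' @export
default_marker_set <- function(m = 104L) {
  if (m < 1L) abort_usage("marker set must contain at least one marker")
  sprintf("BM%03d", seq_len(m))
}

#' Write a tabular report
#'
#' Tab-separated, header first, UTF-8, rows in input order — the one report
#' format every stage of the toolkit emits.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  tryCatch(
    readr::write_tsv(rows, path, progress = FALSE),
    error = function(e) {
      rlang::abort(paste0("cannot write table to ", path, ": ",
                          conditionMessage(e)), class = "magqc_io_error")
    }
  )
  invisible(path)
}

# Two-column TSV with an optional header row matching `cols`.
read_two_col <- function(path, cols) {
  if (!file.exists(path)) {
    abort_validation(paste0("file not found: ", path))
  }
  tab <- readr::read_tsv(path, col_names = cols, col_types = "cc",
                         progress = FALSE)
  if (nrow(tab) > 0L && identical(tolower(unlist(tab[1L, ], use.names = FALSE)),
                                  cols)) {
    tab <- tab[-1L, ]
  }
  tab
}
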