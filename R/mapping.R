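# Read-to-contig mappings. A mapping is a tibble of distinct
# (read_id, contig_id) pairs with the size of the originating read set kept
# as the "total_reads" attribute, because the fraction of reads assembled is
# relative to all reads, mapped or not.

#' Read a read-to-contig mapping
#'
#' Reads an alignment of reads against contigs from either a SAM text stream
#' or a plain two-column TSV (`read_id`, `contig_id`, no header). For SAM,
#' header lines are skipped and records that are unmapped (FLAG bit `0x4`) or
#' secondary/supplementary (`0x100`, `0x800`) are excluded, so each retained
#' pair is a primary alignment. Duplicate (read, contig) pairs collapse to
#' one: a read aligned to the same contig several times counts once, while a
#' read aligned to two contigs keeps both pairs (only distinct read ids enter
#' the reads-assembled fraction).
#'
#' @param path Path to the mapping file.
#' @param format `"sam"`, `"tsv"`, or `"auto"` (default: by file extension,
#'   falling back to TSV).
#' @param total_reads Number of reads in the originating read set, mapped or
#'   not. Must be at least the number of distinct mapped read ids.
#' @return A tibble with columns `read_id`, `contig_id` and attribute
#'   `total_reads`.
#' @export
read_mapping <- function(path, format = c("auto", "sam", "tsv"),
                         total_reads = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_validation(paste0("mapping file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  pairs <- switch(format, sam = parse_sam_pairs(path), tsv = parse_tsv_pairs(path))
  pairs <- dplyr::distinct(pairs)
  as_mapping(pairs, total_reads = total_reads)
}

#' Build a validated mapping from a data frame of pairs
#'
#' @param pairs Data frame with columns `read_id` and `contig_id`.
#' @param total_reads Size of the originating read set; defaults to the
#'   number of distinct mapped read ids (i.e. every read mapped).
#' @return A mapping tibble (see [read_mapping()]).
#' @export
as_mapping <- function(pairs, total_reads = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("read_id", "contig_id") %in% names(pairs)))
  pairs <- dplyr::distinct(
    tibble::tibble(read_id = as.character(pairs$read_id),
                   contig_id = as.character(pairs$contig_id))
  )
  n_mapped <- dplyr::n_distinct(pairs$read_id)
  if (is.null(total_reads)) total_reads <- n_mapped
  total_reads <- as.integer(total_reads)
  if (is.na(total_reads) || total_reads < n_mapped) {
    abort_validation(paste0(
      "total_reads (", total_reads, ") is smaller than the number of ",
      "distinct mapped reads (", n_mapped, ")"
    ))
  }
  attr(pairs, "total_reads") <- total_reads
  pairs
}

# Minimal SAM ingestion: only QNAME, FLAG and RNAME are consumed, and only
# the unmapped/secondary/supplementary flag bits are honoured. Kept as a
# line parse because headerless SAM (which this accepts) cannot go through a
# BAM conversion.
parse_sam_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(read_id = character(), contig_id = character()))
  }
  fields <- stringr::str_split(lines, "\t", n = 4L)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort_format(paste0("SAM record with fewer than 3 fields at alignment line ",
                        which(nf < 3L)[1L]))
  }
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  rname <- vapply(fields, `[[`, character(1), 3L)
  if (any(is.na(flag))) {
    abort_format(paste0("non-numeric FLAG at alignment line ",
                        which(is.na(flag))[1L]))
  }
  keep <- bitwAnd(flag, 0x4L) == 0L &     # mapped
    bitwAnd(flag, 0x100L) == 0L &         # not secondary
    bitwAnd(flag, 0x800L) == 0L &         # not supplementary
    rname != "*"
  tibble::tibble(read_id = qname[keep], contig_id = rname[keep])
}

parse_tsv_pairs <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("read_id", "contig_id"),
                         col_types = "cc", progress = FALSE)
  if (ncol(tab) != 2L) {
    abort_format(paste0("mapping TSV must have exactly 2 columns: ", path))
  }
  tab
}

#' Number of reads in the read set behind a mapping
#'
#' @param mapping A mapping tibble.
#' @return Integer `total_reads` attribute.
#' @export
total_reads <- function(mapping) {
  tr <- attr(mapping, "total_reads")
  if (is.null(tr)) dplyr::n_distinct(mapping$read_id) else tr
}
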