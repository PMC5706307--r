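# Contig sets: the unit of assembly evaluation. A contig set is a tibble with
# one row per sequence (columns id, seq, length, gc) plus a free-text label
# carried as an attribute, so it flows through dplyr verbs unharmed.

#' Read a FASTA file into a contig table
#'
#' Parses a (multi-)FASTA file of reads, contigs or genomes into a tibble with
#' one row per record. Sequences are uppercased on ingest and multi-line
#' records are concatenated. Only the unambiguous nucleotide alphabet
#' `A`, `C`, `G`, `T` plus `N` is accepted; anything else is rejected with the
#' offending record and position named, so corrupt input surfaces immediately
#' rather than as a downstream artifact.
#'
#' @param path Path to a FASTA file.
#' @param label Free-text tag for the set (defaults to the file name). Stored
#'   as the `"label"` attribute and propagated into reports.
#' @return A tibble with columns `id`, `seq`, `length` and `gc` (percent GC of
#'   the `A/C/G/T` bases; `NA` for an all-`N` sequence).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "ACGT", "ACGT", ">c2", "GGGG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    abort_validation(paste0("FASTA file not found: ", path))
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    abort_format(paste0("empty FASTA file: ", path, " (line 1)"))
  }
  if (!startsWith(first, ">")) {
    abort_format(paste0(
      "malformed FASTA: line 1 of ", path, " does not start with '>'"
    ))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_format(paste0("cannot parse FASTA ", path, ": ",
                                            conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort_format(paste0("empty FASTA file: ", path, " (no records)"))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) {
    abort_format(paste0("FASTA record ", which(ids == "")[1L], " in ", path,
                        " has an empty id"))
  }
  seqs <- toupper(as.character(set))
  as_contigs(tibble::tibble(id = ids, seq = unname(seqs)), label = label)
}

#' Build a validated contig table from a data frame
#'
#' Validates ids (non-empty, unique), sequence alphabet (`A/C/G/T/N` after
#' uppercasing) and non-zero length, then adds `length` and `gc` columns.
#'
#' @param x A data frame with columns `id` and `seq`.
#' @param label Free-text set label.
#' @return A contig tibble (see [read_fasta()]).
#' @export
as_contigs <- function(x, label = "contigs") {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  id <- as.character(x$id)
  seq <- toupper(as.character(x$seq))
  if (any(is.na(id) | id == "")) {
    abort_validation("contig ids must be non-empty")
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L) {
    abort_validation(paste0("duplicate sequence id(s): ",
                            paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (any(nchar(seq) == 0L)) {
    abort_validation(paste0("zero-length sequence for id ",
                            id[which(nchar(seq) == 0L)[1L]]))
  }
  bad <- stringr::str_locate(seq, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    abort_validation(paste0(
      "invalid character '", substr(seq[i], bad[i], bad[i]), "' at position ",
      bad[i], " of sequence ", id[i],
      " (alphabet is A/C/G/T/N, case-insensitive)"
    ))
  }
  out <- tibble::tibble(
    id = id,
    seq = seq,
    length = nchar(seq),
    gc = gc_content(seq)
  )
  attr(out, "label") <- label
  out
}

#' Write a contig table to FASTA
#'
#' @param contigs A contig tibble (columns `id`, `seq`).
#' @param path Output path.
#' @param width Line width for wrapping sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(contigs))) {
    writeLines(paste0(">", contigs$id[i]), con)
    s <- contigs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' GC content of nucleotide sequences
#'
#' Percent `G + C` over the unambiguous bases `A/C/G/T`; `N` is excluded from
#' the denominator. Vectorised over sequences.
#'
#' @param seq Character vector of nucleotide sequences (or a contig tibble,
#'   in which case its `seq` column is used).
#' @return Numeric vector of GC percentages; `NA` where a sequence has no
#'   unambiguous base.
#' @examples
#' gc_content(c("ATGC", "AAAA", "ATGN"))
#' @export
gc_content <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$seq
  seq <- toupper(seq)
  gc <- stringr::str_count(seq, "[GC]")
  at <- stringr::str_count(seq, "[AT]")
  denom <- gc + at
  ifelse(denom == 0L, NA_real_, 100 * gc / denom)
}
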