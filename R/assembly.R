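# Assembly continuity statistics and reads-assembled fractions.

#' Contig continuity statistics
#'
#' Computes the classical assembly statistics: number of contigs, total and
#' largest length, mean length, N50 and L50. N50 is the length of the contig
#' at which the cumulative length of contigs, sorted in descending length,
#' first reaches at least half the total assembly length; L50 is the number
#' of contigs in that prefix. Ties on the half-total boundary resolve toward
#' the shorter N50-defining contig (the `>=` convention of QUAST).
#'
#' @param contigs A contig tibble ([read_fasta()]), or any data frame with a
#'   `length` column.
#' @param min_contig Optional minimum contig length filter applied before
#'   the statistics (no filter by default).
#' @return A one-row tibble: `n_contigs`, `total_length`, `largest_contig`,
#'   `mean_length`, `n50`, `l50`.
#' @examples
#' contig_stats(tibble::tibble(length = c(2, 3, 4, 5, 6)))
#' @export
contig_stats <- function(contigs, min_contig = 0L) {
  stopifnot("length" %in% names(contigs))
  len <- as.numeric(contigs$length)
  len <- len[len >= min_contig]
  if (length(len) == 0L) {
    abort_validation("no contigs (after any min_contig filter); cannot compute assembly statistics")
  }
  sorted <- sort(len, decreasing = TRUE)
  csum <- cumsum(sorted)
  l50 <- which(csum >= sum(sorted) / 2)[1L]
  tibble::tibble(
    n_contigs = length(len),
    total_length = sum(len),
    largest_contig = max(len),
    mean_length = mean(len),
    n50 = sorted[l50],
    l50 = l50
  )
}

#' Proportion of reads assembled
#'
#' `100 * distinct mapped read ids / total reads`. A read mapped to several
#' contigs still counts once.
#'
#' @param mapping A mapping tibble ([read_mapping()]).
#' @param total Total reads in the read set; defaults to the mapping's
#'   `total_reads` attribute.
#' @return Percentage in `[0, 100]`.
#' @export
reads_assembled <- function(mapping, total = total_reads(mapping)) {
  if (is.null(total) || total < 1L) {
    abort_validation("total reads must be at least 1")
  }
  n_mapped <- dplyr::n_distinct(mapping$read_id)
  if (total < n_mapped) {
    abort_validation("total reads smaller than the number of distinct mapped reads")
  }
  100 * n_mapped / total
}

#' Per-contig read coverage summary
#'
#' Counts mapped reads per contig and reads per bp, for every contig in the
#' set (contigs with no reads get zero). The overall percent of reads
#' assembled is carried alongside.
#'
#' @param mapping A mapping tibble.
#' @param contigs A contig tibble; every mapped `contig_id` must be present.
#' @param total Total reads (defaults to the mapping attribute).
#' @return An object of class `magqc_coverage`: use [tidy()][generics::tidy]
#'   for the per-contig table and [glance()][generics::glance] for the
#'   one-row summary.
#' @export
coverage_summary <- function(mapping, contigs,
                             total = total_reads(mapping)) {
  unknown <- setdiff(unique(mapping$contig_id), contigs$id)
  if (length(unknown) > 0L) {
    abort_validation(paste0(
      "mapping refers to contig(s) absent from the contig set: ",
      paste(utils::head(unknown, 5L), collapse = ", ")
    ))
  }
  per_contig <- mapping |>
    dplyr::count(.data$contig_id, name = "mapped_read_count") |>
    dplyr::right_join(
      dplyr::select(contigs, contig_id = "id", "length"),
      by = "contig_id"
    ) |>
    dplyr::mutate(
      mapped_read_count = dplyr::coalesce(.data$mapped_read_count, 0L),
      reads_per_bp = .data$mapped_read_count / .data$length
    ) |>
    dplyr::arrange(match(.data$contig_id, contigs$id)) |>
    dplyr::select("contig_id", "mapped_read_count", "reads_per_bp")
  structure(
    list(pct_reads_assembled = reads_assembled(mapping, total),
         per_contig = per_contig),
    class = "magqc_coverage"
  )
}

#' @export
print.magqc_coverage <- function(x, ...) {
  cat(sprintf("<magqc_coverage> %.2f%% of reads assembled; %d contigs\n",
              x$pct_reads_assembled, nrow(x$per_contig)))
  print(x$per_contig, n = 5)
  invisible(x)
}

#' @rdname coverage_summary
#' @param x A `magqc_coverage` object.
#' @param ... Unused.
#' @export
tidy.magqc_coverage <- function(x, ...) x$per_contig

#' @rdname coverage_summary
#' @export
glance.magqc_coverage <- function(x, ...) {
  tibble::tibble(
    pct_reads_assembled = x$pct_reads_assembled,
    n_contigs = nrow(x$per_contig),
    mean_reads_per_bp = mean(x$per_contig$reads_per_bp)
  )
}

#' Contig length distribution plot
#'
#' Histogram of contig lengths on a log10 axis, with N50 marked — the
#' standard visual for comparing assemblies.
#'
#' @param contigs A contig tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(contigs, bins = 40) {
  st <- contig_stats(contigs)
  ggplot2::ggplot(contigs, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = st$n50, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "contig length (bp)", y = "contigs",
                  title = sprintf("N50 = %d bp, L50 = %d",
                                  round(st$n50), st$l50))
}
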