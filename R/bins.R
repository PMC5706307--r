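# Per-bin quality: GC variation, genus composition and richness, and
# single-copy marker completeness/contamination. An ideal bin represents one
# genome: minimal GC spread, low genus richness, completeness near 100%.

#' GC statistics of a bin's contigs
#'
#' Unweighted mean and sample standard deviation (denominator `n - 1`) of
#' per-contig GC percent; contigs with undefined GC (all `N`) are excluded.
#'
#' @param contigs Contig tibble of one bin.
#' @return A one-row tibble `gc_mean`, `gc_sd` (`gc_sd = 0` for a single
#'   contig).
#' @export
bin_gc_stats <- function(contigs) {
  gc <- contigs$gc
  gc <- gc[!is.na(gc)]
  if (length(gc) == 0L) {
    abort_validation("no contig with defined GC content in this bin")
  }
  tibble::tibble(
    gc_mean = mean(gc),
    gc_sd = if (length(gc) == 1L) 0 else stats::sd(gc)
  )
}

#' Per-bin genus abundance tables
#'
#' Joins per-contig taxon assignments onto the bin membership table and
#' tallies genera per bin. Contigs without a classified genus (including
#' contigs absent from `assignments`) are tallied as `UNASSIGNED`. Counts
#' are one per contig by default, or total bp with `weight = "length"`
#' (requires `contigs`).
#'
#' @param assignments Per-contig taxon table ([classify_contigs()] output or
#'   any data frame with `contig_id` and `genus`).
#' @param bins Bin membership tibble (`contig_id`, `bin_id`).
#' @param contigs Contig tibble, needed for length weighting.
#' @param weight `"count"` (default) or `"length"`.
#' @return A tibble `bin_id`, `genus`, `count` (genus `"UNASSIGNED"` carries
#'   the unclassified mass).
#' @export
bin_taxon_table <- function(assignments, bins, contigs = NULL,
                            weight = c("count", "length")) {
  weight <- match.arg(weight)
  bins <- as_bins(bins)
  tab <- bins |>
    dplyr::left_join(
      dplyr::select(assignments, "contig_id", "genus"),
      by = "contig_id"
    ) |>
    dplyr::mutate(genus = dplyr::coalesce(.data$genus, "UNASSIGNED"))
  if (weight == "length") {
    if (is.null(contigs)) {
      abort_usage("length weighting requires the contig table")
    }
    tab <- dplyr::left_join(
      tab, dplyr::select(contigs, contig_id = "id", "length"),
      by = "contig_id"
    )
    if (any(is.na(tab$length))) {
      abort_validation("bin contains contig ids absent from the contig set")
    }
    tab |>
      dplyr::group_by(.data$bin_id, .data$genus) |>
      dplyr::summarise(count = sum(.data$length), .groups = "drop")
  } else {
    dplyr::count(tab, .data$bin_id, .data$genus, name = "count")
  }
}

#' Marker-based completeness and contamination
#'
#' Against a set of `M` universal single-copy markers:
#' `completeness = 100 * (distinct markers present) / M` and
#' `contamination = 100 * sum(copy_count - 1) / M` over markers present more
#' than once. A bin with every marker present exactly once is 100% complete
#' and 0% contaminated.
#'
#' @param hits Marker-hit tibble (`bin_id`, `marker_id`, `copy_count`).
#' @param marker_ids The marker universe (default [default_marker_set()]).
#' @param bin_ids Bins to report (default: all bins in `hits`); a bin with
#'   no hits reports 0 / 0.
#' @return A tibble `bin_id`, `n_markers_found`, `completeness`,
#'   `contamination`.
#' @export
completeness_contamination <- function(hits,
                                       marker_ids = default_marker_set(),
                                       bin_ids = NULL) {
  hits <- as_marker_hits(hits)
  M <- length(marker_ids)
  outside <- setdiff(unique(hits$marker_id), marker_ids)
  if (length(outside) > 0L) {
    abort_validation(paste0("marker hit(s) outside the marker set: ",
                            paste(utils::head(outside, 5L), collapse = ", ")))
  }
  if (is.null(bin_ids)) bin_ids <- unique(hits$bin_id)
  hits |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      n_markers_found = dplyr::n_distinct(.data$marker_id),
      completeness = 100 * .data$n_markers_found / M,
      contamination = 100 * sum(pmax(.data$copy_count - 1L, 0L)) / M,
      .groups = "drop"
    ) |>
    dplyr::right_join(tibble::tibble(bin_id = bin_ids), by = "bin_id") |>
    dplyr::mutate(dplyr::across(
      c("n_markers_found", "completeness", "contamination"),
      \(x) dplyr::coalesce(x, 0)
    )) |>
    dplyr::arrange(match(.data$bin_id, bin_ids))
}

#' Full per-bin quality report
#'
#' One row per bin joining contig statistics (count, total bp, GC mean and
#' spread), genus composition (richness as both Margalef index and raw genus
#' count, dominant genus and its share, unassigned fraction) and
#' marker-based completeness/contamination. The dominant share is
#' length-weighted (fraction of the bin's bp attributed to its top genus,
#' unassigned bp included in the denominator), which is what the
#' MAG-versus-novel classification consumes; the unassigned fraction is by
#' contig count.
#'
#' @param contigs Contig tibble covering every binned contig.
#' @param bins Bin membership tibble (`contig_id`, `bin_id`).
#' @param assignments Per-contig taxon table ([classify_contigs()]).
#' @param hits Marker-hit tibble; may be `NULL` (completeness columns `NA`).
#' @param marker_ids Marker universe (default [default_marker_set()]).
#' @return A tibble with one row per bin: `bin_id`, `n_contigs`, `total_bp`,
#'   `gc_mean`, `gc_sd`, `genus_count`, `genus_richness`, `dominant_genus`,
#'   `dominant_share`, `unassigned_fraction`, `n_markers_found`,
#'   `completeness`, `contamination`.
#' @export
bin_quality <- function(contigs, bins, assignments, hits = NULL,
                        marker_ids = default_marker_set()) {
  bins <- as_bins(bins)
  missing_ids <- setdiff(bins$contig_id, contigs$id)
  if (length(missing_ids) > 0L) {
    abort_validation(paste0("binned contig(s) absent from the contig set: ",
                            paste(utils::head(missing_ids, 5L), collapse = ", ")))
  }
  base <- bins |>
    dplyr::left_join(dplyr::select(contigs, contig_id = "id", "length", "gc"),
                     by = "contig_id") |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      n_contigs = dplyr::n(),
      total_bp = sum(.data$length),
      gc_mean = mean(.data$gc, na.rm = TRUE),
      gc_sd = ifelse(sum(!is.na(.data$gc)) <= 1L, 0,
                     stats::sd(.data$gc, na.rm = TRUE)),
      .groups = "drop"
    )

  by_bp <- bin_taxon_table(assignments, bins, contigs = contigs,
                           weight = "length")
  by_n <- bin_taxon_table(assignments, bins, weight = "count")

  comp <- by_bp |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      dominant_genus = {
        cl <- .data$genus[.data$genus != "UNASSIGNED"]
        w <- .data$count[.data$genus != "UNASSIGNED"]
        if (length(cl) == 0L) "NONE" else cl[order(-w, cl)][1L]
      },
      dominant_share = {
        w <- .data$count[.data$genus != "UNASSIGNED"]
        if (length(w) == 0L) 0 else max(w) / sum(.data$count)
      },
      .groups = "drop"
    )
  rich <- by_n |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      genus_count = sum(.data$genus != "UNASSIGNED"),
      genus_richness = {
        n <- .data$count[.data$genus != "UNASSIGNED"]
        if (length(n) == 0L) NA_real_ else diversity_indices(n)$margalef_d
      },
      unassigned_fraction = sum(.data$count[.data$genus == "UNASSIGNED"]) /
        sum(.data$count),
      .groups = "drop"
    )

  out <- base |>
    dplyr::left_join(rich, by = "bin_id") |>
    dplyr::left_join(comp, by = "bin_id")
  if (!is.null(hits)) {
    cc <- completeness_contamination(hits, marker_ids,
                                     bin_ids = unique(bins$bin_id))
    out <- dplyr::left_join(out, cc, by = "bin_id")
  } else {
    out$n_markers_found <- NA_real_
    out$completeness <- NA_real_
    out$contamination <- NA_real_
  }
  out
}

#' Bin quality overview plot
#'
#' GC spread against completeness, point size by bin size — the at-a-glance
#' view separating clean, complete bins from mixed ones.
#'
#' @param quality Output of [bin_quality()], optionally with a `label`
#'   column from [classify_bins()] to colour by.
#' @return A ggplot object.
#' @export
plot_bin_quality <- function(quality) {
  aes <- ggplot2::aes(x = .data$gc_sd, y = .data$completeness,
                      size = .data$total_bp)
  if ("label" %in% names(quality)) {
    aes$colour <- rlang::quo(.data$label)
  }
  ggplot2::ggplot(quality, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "GC standard deviation (percentage points)",
                  y = "marker completeness (%)", size = "bin size (bp)")
}
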