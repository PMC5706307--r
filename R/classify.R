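# Rule-based bin classification. A bin dominated by a single genus is a
# metagenome-assembled genome (MAG); a bin that fails the dominance rule but
# carries most of the single-copy markers is a potentially novel genome
# (well-assembled genetic material that composition profiling cannot place);
# everything else is a mixed bin.

MAG_LABELS <- c("MAG", "POTENTIALLY_NOVEL", "MIXED")

#' Classify bins as MAG, potentially novel, or mixed
#'
#' Rules, evaluated in order per bin:
#' 1. `MAG` if `dominant_share >= mag_dominance` and a dominant genus exists;
#' 2. `POTENTIALLY_NOVEL` if `completeness >= novel_min_completeness`
#'    (default 50%) while the dominance rule failed;
#' 3. `MIXED` otherwise.
#'
#' @param quality Output of [bin_quality()] (needs `dominant_genus`,
#'   `dominant_share`, `completeness`).
#' @param config A [magqc_config()] carrying `mag_dominance` and
#'   `novel_min_completeness`.
#' @return `quality` with `label` and `rationale` columns appended; labels
#'   are the stable strings `"MAG"`, `"POTENTIALLY_NOVEL"`, `"MIXED"`.
#' @export
classify_bins <- function(quality, config = magqc_config()) {
  need <- c("bin_id", "dominant_genus", "dominant_share", "completeness")
  if (!all(need %in% names(quality))) {
    abort_validation(paste0("bin quality table lacks column(s): ",
                            paste(setdiff(need, names(quality)), collapse = ", ")))
  }
  if (any(is.na(quality$dominant_share)) || any(is.na(quality$completeness))) {
    abort_validation("dominant_share and completeness must be populated for every bin")
  }
  theta <- config$mag_dominance
  cmin <- config$novel_min_completeness
  quality |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$dominant_share >= theta & .data$dominant_genus != "NONE" ~ "MAG",
        .data$completeness >= cmin ~ "POTENTIALLY_NOVEL",
        TRUE ~ "MIXED"
      ),
      rationale = dplyr::case_when(
        .data$label == "MAG" ~
          sprintf("single_genus_dominance: %s share %.2f >= %.2f",
                  .data$dominant_genus, .data$dominant_share, theta),
        .data$label == "POTENTIALLY_NOVEL" ~
          sprintf("complete_but_unannotated: completeness %.1f >= %.1f, dominance %.2f < %.2f",
                  .data$completeness, cmin, .data$dominant_share, theta),
        TRUE ~
          sprintf("mixed_residual: dominance %.2f < %.2f and completeness %.1f < %.1f",
                  .data$dominant_share, theta, .data$completeness, cmin)
      )
    )
}

#' Project-level bin summary
#'
#' Counts and percentages of MAG and potentially novel bins, plus the
#' per-genus table of bins in which that genus exceeds the display
#' threshold (default 20% within-bin share).
#'
#' @param labelled Output of [classify_bins()].
#' @param genus_tables Per-bin genus tables ([bin_taxon_table()]), used for
#'   the display-threshold genus listing; optional.
#' @param display_threshold Minimum within-bin genus share for the genus
#'   table (default 0.20).
#' @return An object of class `magqc_summary`; `glance()` gives the one-row
#'   project summary (percentages rounded to 2 decimals), `tidy()` the genus
#'   table.
#' @export
summarize_project <- function(labelled, genus_tables = NULL,
                              display_threshold = 0.20) {
  if (nrow(labelled) == 0L) abort_validation("no bins to summarise")
  n_bins <- nrow(labelled)
  n_mag <- sum(labelled$label == "MAG")
  n_novel <- sum(labelled$label == "POTENTIALLY_NOVEL")
  genus_tab <- tibble::tibble(genus = character(), n_bins = integer())
  if (!is.null(genus_tables)) {
    genus_tab <- genus_tables |>
      dplyr::group_by(.data$bin_id) |>
      dplyr::mutate(share = .data$count / sum(.data$count)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$genus != "UNASSIGNED",
                    .data$share > display_threshold) |>
      dplyr::count(.data$genus, name = "n_bins") |>
      dplyr::arrange(dplyr::desc(.data$n_bins), .data$genus)
  }
  structure(list(
    n_bins = n_bins,
    n_mag = n_mag,
    pct_mag = round(100 * n_mag / n_bins, 2),
    n_novel = n_novel,
    pct_novel = round(100 * n_novel / n_bins, 2),
    n_mixed = n_bins - n_mag - n_novel,
    genus_table = genus_tab
  ), class = "magqc_summary")
}

#' @export
print.magqc_summary <- function(x, ...) {
  cat(sprintf(
    "<magqc_summary> %d bins: %d MAG (%.2f%%), %d potentially novel (%.2f%%), %d mixed\n",
    x$n_bins, x$n_mag, x$pct_mag, x$n_novel, x$pct_novel, x$n_mixed))
  invisible(x)
}

#' @rdname summarize_project
#' @param x A `magqc_summary` object.
#' @param ... Unused.
#' @export
glance.magqc_summary <- function(x, ...) {
  tibble::tibble(n_bins = x$n_bins, n_mag = x$n_mag, pct_mag = x$pct_mag,
                 n_novel = x$n_novel, pct_novel = x$pct_novel,
                 n_mixed = x$n_mixed)
}

#' @rdname summarize_project
#' @export
tidy.magqc_summary <- function(x, ...) x$genus_table
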