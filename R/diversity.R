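# Taxon diversity indices and the reads-vs-contigs chimerism contrast.
# An assembler should conserve taxon richness while (if anything) increasing
# evenness; a substantial drop in richness from reads to contigs indicates
# chimeric contigs, whose blended composition keeps them unclassified.

#' Diversity indices of an abundance table
#'
#' Margalef richness `d = (S - 1) / log(N)`, Shannon entropy
#' `H' = -sum p_i log p_i`, Pielou evenness `J' = H' / log(S)` and the
#' Simpson complement `1 - D = 1 - sum p_i^2`, computed over taxa with
#' positive counts. Natural logarithms by default (`log_base` overrides,
#' affecting `H'` and `d`; `J'` is base-invariant and kept in nats/`log_base`
#' consistently). Margalef is 0 when `N = 1`; Pielou is `NA` when `S = 1`
#' (undefined: a one-taxon community has no evenness).
#'
#' @param counts A data frame with columns `taxon_id` and `count`, or a
#'   (possibly named) non-negative numeric vector of counts.
#' @param log_base Logarithm base (default `exp(1)`).
#' @return A one-row tibble: `S`, `N`, `margalef_d`, `shannon_h`, `pielou_j`,
#'   `simpson_1minusD`.
#' @examples
#' diversity_indices(c(25, 25, 25, 25))
#' @export
diversity_indices <- function(counts, log_base = exp(1)) {
  n <- as_count_vector(counts)
  n <- n[n > 0]
  if (length(n) == 0L) {
    abort_validation("abundance table has no positive count")
  }
  S <- length(n)
  N <- sum(n)
  p <- n / N
  H <- -sum(p * log(p, base = log_base))
  tibble::tibble(
    S = S,
    N = N,
    margalef_d = if (N == 1) 0 else (S - 1) / log(N, base = log_base),
    shannon_h = H,
    pielou_j = if (S == 1) NA_real_ else H / log(S, base = log_base),
    simpson_1minusD = 1 - sum(p^2)
  )
}

as_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    col <- intersect(c("count", "n", "abundance"), names(counts))
    if (length(col) == 0L) {
      abort_validation("abundance table needs a count/n/abundance column")
    }
    n <- as.numeric(counts[[col[1L]]])
  } else {
    n <- as.numeric(counts)
  }
  if (any(is.na(n)) || any(n < 0)) {
    abort_validation("counts must be non-negative and non-missing")
  }
  n
}

#' Diversity-based contig chimerism test
#'
#' Contrasts taxon richness and evenness between a read-level and a
#' contig-level taxon profile of the same sample. The point contrast is
#' `delta = contigs - reads` in Margalef richness and Pielou evenness; an
#' uncertainty interval for the richness contrast comes from a seeded
#' bootstrap that resamples the `N` classified items of each table
#' independently `B` times. Chimerism is flagged when the whole 95% interval
#' for `delta_richness` lies below zero — richness significantly lost in
#' assembly, the signature of chimera formation. A richness-conserving
#' assembly with increased evenness is the expected healthy outcome.
#'
#' @param reads_profile,contigs_profile Abundance tables (see
#'   [diversity_indices()]): taxon counts from classified reads and from
#'   classified contigs.
#' @param B Bootstrap replicates (>= 100; default 1000).
#' @param seed Integer seed making the interval reproducible.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `magqc_chimerism`; see
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot.magqc_chimerism()].
#' @export
assess_chimerism <- function(reads_profile, contigs_profile, B = 1000L,
                             seed = 1L, conf = 0.95) {
  B <- as.integer(B)
  if (B < 100L) {
    abort_usage("B must be at least 100 (percentile interval unstable below)")
  }
  r <- as_count_vector(reads_profile)
  ct <- as_count_vector(contigs_profile)
  div_r <- diversity_indices(r)
  div_c <- diversity_indices(ct)

  boot_margalef <- function(n, B) {
    n <- n[n > 0]
    N <- sum(n)
    draws <- stats::rmultinom(B, size = N, prob = n / N)
    S_b <- colSums(draws > 0)
    if (N == 1) rep(0, B) else (S_b - 1) / log(N)
  }
  delta_boot <- withr::with_seed(seed, {
    boot_margalef(ct, B) - boot_margalef(r, B)
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(delta_boot, c(alpha, 1 - alpha), type = 7))

  structure(list(
    reads = div_r,
    contigs = div_c,
    delta_richness = div_c$margalef_d - div_r$margalef_d,
    delta_evenness = div_c$pielou_j - div_r$pielou_j,
    ci_low = ci[1L],
    ci_high = ci[2L],
    chimerism_flag = ci[2L] < 0,
    B = B, seed = seed, conf = conf,
    delta_boot = delta_boot
  ), class = "magqc_chimerism")
}

#' @export
print.magqc_chimerism <- function(x, ...) {
  cat("<magqc_chimerism>\n")
  cat(sprintf("  delta richness (contigs - reads): %.4f [%.4f, %.4f]\n",
              x$delta_richness, x$ci_low, x$ci_high))
  cat(sprintf("  delta evenness: %s\n",
              ifelse(is.na(x$delta_evenness), "NA",
                     sprintf("%.4f", x$delta_evenness))))
  cat(sprintf("  chimerism flagged: %s\n", x$chimerism_flag))
  invisible(x)
}

#' @rdname assess_chimerism
#' @param x A `magqc_chimerism` object.
#' @param ... Unused.
#' @export
tidy.magqc_chimerism <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$reads, level = "reads", .before = 1),
    dplyr::mutate(x$contigs, level = "contigs", .before = 1)
  )
}

#' @rdname assess_chimerism
#' @export
glance.magqc_chimerism <- function(x, ...) {
  tibble::tibble(
    delta_richness = x$delta_richness,
    delta_evenness = x$delta_evenness,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    chimerism_flag = x$chimerism_flag,
    B = x$B,
    seed = x$seed
  )
}

#' Plot the bootstrap richness contrast
#'
#' Histogram of the bootstrap distribution of `delta_richness` with the
#' percentile interval and zero marked.
#'
#' @param object A `magqc_chimerism` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.magqc_chimerism <- function(object, ...) {
  df <- tibble::tibble(delta = object$delta_boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "firebrick") +
    ggplot2::labs(
      x = "bootstrap delta Margalef richness (contigs - reads)", y = "replicates",
      title = sprintf("chimerism %s", ifelse(object$chimerism_flag,
                                             "flagged", "not flagged"))
    )
}
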