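# End-to-end driver: assembly evaluation -> composition profiling ->
# diversity/chimerism -> bin evaluation -> classification, with one
# consolidated summary and a run manifest. Every stage output is a pure
# function of (inputs, config, seed), so a re-run reproduces it exactly.

#' Run the full quality-control workflow
#'
#' Executes the evaluation stages in pipeline order on file inputs and
#' writes one TSV per stage plus `summary.tsv` and `manifest.json` under
#' `outdir`. Contigs are required; the read set, mapping, reference
#' signatures, bins and marker hits are optional, and stages whose inputs
#' are missing are skipped cleanly (recorded in the manifest). The
#' read-level taxon table for the chimerism contrast comes from the
#' non-negative least squares mixture estimate on the read set, scaled to
#' read counts; the contig-level table counts classified contigs.
#'
#' @param contigs Path to the contig FASTA (required).
#' @param reads Path to the read FASTA (optional; enables chimerism).
#' @param mapping Path to a SAM/TSV read mapping (optional).
#' @param total_reads Total reads behind `mapping` (optional; defaults to
#'   the number of reads in `reads`, else distinct mapped reads).
#' @param signatures Path to a reference-signature TSV (optional; enables
#'   profiling, chimerism and bin taxonomy).
#' @param bins Path to a bin membership TSV (optional).
#' @param markers Path to a marker-hit TSV (optional).
#' @param outdir Output directory.
#' @param config A [magqc_config()].
#' @param seed Integer seed for the bootstrap stage (default: the config's
#'   `rng_seed`).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_workflow <- function(contigs, reads = NULL, mapping = NULL,
                         total_reads = NULL, signatures = NULL, bins = NULL,
                         markers = NULL, outdir, config = magqc_config(),
                         seed = config$rng_seed) {
  if (missing(contigs) || is.null(contigs)) {
    abort_usage("stage assembly-eval: a contig FASTA is required")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list(contigs = contigs, reads = reads, mapping = mapping,
                 signatures = signatures, bins = bins, markers = markers)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    toolkit = paste0("magqc ", as.character(utils::packageVersion("magqc"))),
    seed = seed,
    config = unclass(config),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list()
  )
  res <- list()
  on.exit(jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                               auto_unbox = TRUE, pretty = TRUE, digits = NA))
  stage <- function(name, enabled, fn) {
    if (!enabled) {
      manifest$stages[[name]] <<- "skipped"
      return(NULL)
    }
    out <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- paste0("failed: ", conditionMessage(e))
      rlang::abort(paste0("stage ", name, " failed: ", conditionMessage(e)),
                   parent = e)
    })
    manifest$stages[[name]] <<- "ok"
    out
  }

  ctg <- read_fasta(contigs)
  rds <- if (!is.null(reads)) read_fasta(reads)
  refs <- if (!is.null(signatures)) read_signatures(signatures)

  res$assembly <- stage("assembly-eval", TRUE, function() {
    st <- contig_stats(ctg)
    if (!is.null(mapping)) {
      mp <- read_mapping(mapping,
                         total_reads = total_reads %||%
                           (if (!is.null(rds)) nrow(rds)))
      st$pct_reads_assembled <- reads_assembled(mp)
    } else {
      st$pct_reads_assembled <- NA_real_
    }
    write_table(st, file.path(outdir, "assembly_stats.tsv"))
    st
  })

  res$assignments <- stage("profile", !is.null(refs), function() {
    asn <- classify_contigs(ctg, refs, tau = config$assign_min_similarity,
                            k = signatures_k(refs))
    write_table(asn, file.path(outdir, "contig_taxa.tsv"))
    asn
  })

  res$chimerism <- stage("diversity", !is.null(refs) && !is.null(rds), function() {
    read_mix <- estimate_abundances(kmer_profile(rds, k = signatures_k(refs)),
                                    refs)
    reads_counts <- dplyr::transmute(
      read_mix, taxon_id = .data$taxon_id,
      count = round(.data$abundance * nrow(rds)))
    contig_counts <- res$assignments |>
      dplyr::filter(.data$taxon_id != "UNASSIGNED") |>
      dplyr::count(.data$taxon_id, name = "count")
    rep <- assess_chimerism(reads_counts, contig_counts,
                            B = config$bootstrap_B, seed = seed)
    write_table(glance(rep), file.path(outdir, "chimerism.tsv"))
    rep
  })

  res$quality <- stage("bin-eval",
                       !is.null(bins) && !is.null(res$assignments), function() {
    bn <- read_bins(bins)
    hits <- if (!is.null(markers)) read_marker_hits(markers)
    q <- bin_quality(ctg, bn, res$assignments, hits = hits)
    write_table(q, file.path(outdir, "bin_quality.tsv"))
    q
  })

  res$labels <- stage("classify", !is.null(res$quality) &&
                        all(!is.na(res$quality$completeness)), function() {
    lab <- classify_bins(res$quality, config)
    write_table(dplyr::select(lab, "bin_id", "label", "rationale"),
                file.path(outdir, "bin_labels.tsv"))
    gt <- bin_taxon_table(res$assignments, read_bins(bins))
    summ <- summarize_project(lab, genus_tables = gt)
    write_table(glance(summ), file.path(outdir, "project_summary.tsv"))
    write_table(tidy(summ), file.path(outdir, "genus_table.tsv"))
    list(labels = lab, summary = summ)
  })

  # consolidated per-bin summary alongside the assembly-level row
  summary_tab <- res$assembly
  if (!is.null(res$chimerism)) {
    summary_tab <- dplyr::bind_cols(summary_tab, glance(res$chimerism))
  }
  write_table(summary_tab, file.path(outdir, "summary.tsv"))
  if (!is.null(res$labels)) {
    write_table(res$labels$labels, file.path(outdir, "bin_summary.tsv"))
  }
  res$manifest <- manifest
  invisible(res)
}
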