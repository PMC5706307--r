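#' Toolkit configuration
#'
#' Collects every tunable threshold of the toolkit in one validated list.
#' Defaults follow the conventions of the tools the workflow emulates:
#' kmer size 6 for mixture profiling and 4 (tetranucleotide) for per-contig
#' assignment; the ANIb fragment length (1020 bp), 30% identity and 70%
#' coverage filters of the JSpecies convention; the > 95% ANI species
#' boundary; a genus-dominance threshold of 0.8 for calling a bin a
#' metagenome-assembled genome; and the 50% completeness floor for
#' potentially novel genomes.
#'
#' @param kmer_size_profile Kmer size for mixture estimation (2-8, default 6).
#' @param kmer_size_assign Kmer size for per-contig assignment (2-8, default 4).
#' @param assign_min_similarity Minimum profile correlation `tau` for a
#'   contig to be assigned (default 0.8).
#' @param mag_dominance Minimum dominant-genus share for the MAG call
#'   (default 0.8).
#' @param novel_min_completeness Completeness floor (percent) for the
#'   potentially-novel call (default 50).
#' @param ani_fragment_len ANIb fragment length in bp (default 1020).
#' @param ani_min_identity Per-fragment identity filter (default 0.3).
#' @param ani_min_coverage Per-fragment coverage filter (default 0.7).
#' @param species_ani_threshold ANI percent above which two genomes are the
#'   same species (strictly greater than; default 95).
#' @param bootstrap_B Bootstrap replicates for the chimerism contrast
#'   (default 1000).
#' @param rng_seed Integer seed used by seeded operations when no explicit
#'   seed is given (default 1).
#' @return A list of class `magqc_config`.
#' @examples
#' cfg <- magqc_config(mag_dominance = 0.9)
#' cfg$mag_dominance
#' @export
magqc_config <- function(kmer_size_profile = 6L,
                         kmer_size_assign = 4L,
                         assign_min_similarity = 0.8,
                         mag_dominance = 0.8,
                         novel_min_completeness = 50,
                         ani_fragment_len = 1020L,
                         ani_min_identity = 0.3,
                         ani_min_coverage = 0.7,
                         species_ani_threshold = 95,
                         bootstrap_B = 1000L,
                         rng_seed = 1L) {
  cfg <- list(
    kmer_size_profile = as.integer(kmer_size_profile),
    kmer_size_assign = as.integer(kmer_size_assign),
    assign_min_similarity = as.numeric(assign_min_similarity),
    mag_dominance = as.numeric(mag_dominance),
    novel_min_completeness = as.numeric(novel_min_completeness),
    ani_fragment_len = as.integer(ani_fragment_len),
    ani_min_identity = as.numeric(ani_min_identity),
    ani_min_coverage = as.numeric(ani_min_coverage),
    species_ani_threshold = as.numeric(species_ani_threshold),
    bootstrap_B = as.integer(bootstrap_B),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "magqc_config")
}

validate_config <- function(cfg) {
  in01 <- function(x) is.finite(x) && x >= 0 && x <= 1
  if (!in01(cfg$assign_min_similarity)) {
    abort_usage("assign_min_similarity must be in [0, 1]")
  }
  if (!in01(cfg$mag_dominance)) abort_usage("mag_dominance must be in [0, 1]")
  if (!in01(cfg$ani_min_identity)) abort_usage("ani_min_identity must be in [0, 1]")
  if (!in01(cfg$ani_min_coverage)) abort_usage("ani_min_coverage must be in [0, 1]")
  for (ks in c("kmer_size_profile", "kmer_size_assign")) {
    if (cfg[[ks]] < 2L || cfg[[ks]] > 8L) {
      abort_usage(paste0(ks, " must be in [2, 8]"))
    }
  }
  if (cfg$ani_fragment_len < 100L) {
    abort_usage("ani_fragment_len must be at least 100 bp")
  }
  if (cfg$novel_min_completeness < 0 || cfg$novel_min_completeness > 100) {
    abort_usage("novel_min_completeness is a percentage in [0, 100]")
  }
  if (cfg$species_ani_threshold < 0 || cfg$species_ani_threshold > 100) {
    abort_usage("species_ani_threshold is a percentage in [0, 100]")
  }
  if (cfg$bootstrap_B < 1L) abort_usage("bootstrap_B must be positive")
  invisible(cfg)
}

#' Read a configuration file
#'
#' YAML key-value file whose keys are the arguments of [magqc_config()];
#' unknown keys are rejected. Values given in `...` override the file.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param ... Overrides passed to [magqc_config()].
#' @return A `magqc_config` list.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_usage(paste0("config file not found: ", path))
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(magqc_config)))
    if (length(unknown) > 0L) {
      abort_usage(paste0("unknown config key(s): ",
                         paste(unknown, collapse = ", ")))
    }
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(magqc_config, vals)
}

#' @export
print.magqc_config <- function(x, ...) {
  cat("<magqc_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
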