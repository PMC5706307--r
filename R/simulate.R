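# Seeded community simulator. Generates genomes (i.i.d. or with a
# per-genome second-order Markov composition bias), mutated relatives,
# Illumina-like / IonTorrent-like read sets, contig sets with chimera
# injection, bins of known marker content, and reference signatures —
# everything downstream of assembly/binning is thereby testable against
# known ground truth, with no external database.

BASES <- c("A", "C", "G", "T")

platform_params <- function(platform) {
  switch(platform,
    illumina_like = list(read_length = 250L, error_rate = 0.001, indels = FALSE),
    iontorrent_like = list(read_length = 200L, error_rate = 0.01, indels = TRUE),
    abort_usage(paste0("unknown platform: ", platform,
                       " (use illumina_like or iontorrent_like)"))
  )
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc` split evenly (and likewise
#' for A/T), or — with `bias_beta` set — from a second-order Markov chain
#' carrying a per-genome, composition-neutral word bias: for each of the 16
#' dinucleotide contexts, the fixed GC mass `gc` is split between G and C
#' (and the AT mass between A and T) by Beta(`bias_beta`, `bias_beta`)
#' draws made once per genome. Because every context keeps
#' `P(G) + P(C) = gc` exactly, local GC content never drifts along the
#' genome (the signature is homogeneous, as in real genomes), while the
#' context-specific G/C and A/T preferences give each genome a strong,
#' distinctive tetranucleotide fingerprint.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc Target GC fraction, strictly inside (0, 1).
#' @param seed Integer seed; the same seed always yields the same genome.
#' @param bias_beta Beta concentration of the per-context base splits
#'   (1 = uniform splits, strong signature; larger = weaker signature), or
#'   `NULL` (default) for i.i.d. bases with no signature.
#' @return A nucleotide string.
#' @export
generate_genome <- function(length, gc, seed, bias_beta = NULL) {
  length <- as.integer(length)
  if (length < 1000L) abort_usage("genome length must be >= 1000 bp")
  if (!is.finite(gc) || gc <= 0 || gc >= 1) {
    abort_usage("gc must lie strictly between 0 and 1")
  }
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  withr::with_seed(seed, {
    if (is.null(bias_beta)) {
      paste(sample(BASES, length, replace = TRUE, prob = p0), collapse = "")
    } else {
      # 16 contexts = previous two bases; per context, the A-share of the
      # AT mass and the C-share of the GC mass are Beta(a, a) draws
      a_share <- stats::rbeta(16L, bias_beta, bias_beta)
      c_share <- stats::rbeta(16L, bias_beta, bias_beta)
      P <- cbind((1 - gc) * a_share, gc * c_share,
                 gc * (1 - c_share), (1 - gc) * (1 - a_share))
      cum <- t(apply(P, 1L, cumsum))
      out <- integer(length)
      out[1:2] <- sample.int(4L, 2L, replace = TRUE, prob = p0)
      u <- stats::runif(length)
      for (i in 3:length) {
        ctx <- (out[i - 2L] - 1L) * 4L + out[i - 1L]
        out[i] <- findInterval(u[i], cum[ctx, ]) + 1L
      }
      paste(BASES[out], collapse = "")
    }
  })
}

#' Mutate a genome by random substitutions
#'
#' Each site is substituted independently with probability `sub_rate` to a
#' uniformly chosen different base. The edit list is returned so downstream
#' identity measurements can be checked against the exact edits.
#'
#' @param seq Nucleotide string.
#' @param sub_rate Per-site substitution probability in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return A list: `seq` (mutated string) and `edits`
#'   (tibble `pos`, `ref`, `alt`).
#' @export
mutate_genome <- function(seq, sub_rate, seed) {
  if (is.data.frame(seq)) seq <- seq$seq[1L]
  if (sub_rate < 0 || sub_rate > 0.5) abort_usage("sub_rate must be in [0, 0.5]")
  n <- nchar(seq)
  withr::with_seed(seed, {
    pos <- which(stats::runif(n) < sub_rate)
    if (length(pos) == 0L) {
      return(list(seq = seq,
                  edits = tibble::tibble(pos = integer(), ref = character(),
                                         alt = character())))
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    ref <- chars[pos]
    # uniform among the three other bases
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1),
                  USE.NAMES = FALSE)
    chars[pos] <- alt
    list(seq = paste(chars, collapse = ""),
         edits = tibble::tibble(pos = pos, ref = ref, alt = alt))
  })
}

#' Specify a synthetic community
#'
#' The axes the simulator controls mirror the contrasts of real projects:
#' number of genomes (taxonomic diversity), per-genome GC, pairwise
#' divergence, abundance skew and sequencing platform (Illumina-like:
#' 250 bp reads, 0.1% error; IonTorrent-like: 200 bp reads, 1% error with
#' indels).
#'
#' @param n_genomes Number of community genomes.
#' @param genome_length Length of each genome (bp).
#' @param gc_targets Per-genome GC fractions (recycled); default spreads
#'   0.35-0.65 so genomes are compositionally distinguishable.
#' @param divergence Optional pairwise substitution divergence in
#'   `[0, 0.5]`: when set, genomes are mutated copies of one ancestor
#'   (each lineage at `divergence / 2`); when `NULL` (default), genomes are
#'   generated independently, each with its own word bias.
#' @param abundances Relative abundances (must sum to 1); default uniform.
#' @param platform `"illumina_like"` or `"iontorrent_like"`.
#' @param bias_beta Per-genome word-bias strength passed to
#'   [generate_genome()] (default 1; only used when `divergence` is `NULL`).
#' @param seed Integer seed.
#' @return A list of class `magqc_community_spec`.
#' @export
community_spec <- function(n_genomes = 10L,
                           genome_length = 1e5,
                           gc_targets = seq(0.35, 0.65, length.out = n_genomes),
                           divergence = NULL,
                           abundances = rep(1 / n_genomes, n_genomes),
                           platform = c("illumina_like", "iontorrent_like"),
                           bias_beta = 1,
                           seed = 1L) {
  platform <- match.arg(platform)
  n_genomes <- as.integer(n_genomes)
  if (n_genomes < 1L) abort_usage("n_genomes must be >= 1")
  gc_targets <- rep_len(gc_targets, n_genomes)
  if (abs(sum(abundances) - 1) > 1e-8) {
    abort_usage("abundances must sum to 1")
  }
  if (length(abundances) != n_genomes) {
    abort_usage("abundances must have one entry per genome")
  }
  if (!is.null(divergence) && (divergence < 0 || divergence > 0.5)) {
    abort_usage("divergence must be in [0, 0.5]")
  }
  structure(list(
    n_genomes = n_genomes, genome_length = as.integer(genome_length),
    gc_targets = gc_targets, divergence = divergence,
    abundances = abundances, platform = platform,
    bias_beta = bias_beta, seed = as.integer(seed)
  ), class = "magqc_community_spec")
}

#' Build the genomes of a community
#'
#' @param spec A [community_spec()].
#' @return A genome tibble (`id`, `genus`, `seq`, `length`, `gc`); ids
#'   `genome_01` ... and one genus per genome (`Genus01` ...).
#' @export
build_community <- function(spec) {
  stopifnot(inherits(spec, "magqc_community_spec"))
  n <- spec$n_genomes
  ids <- sprintf("genome_%02d", seq_len(n))
  seqs <- if (is.null(spec$divergence)) {
    lapply(seq_len(n), function(i) {
      generate_genome(spec$genome_length, spec$gc_targets[i],
                      seed = spec$seed + i, bias_beta = spec$bias_beta)
    })
  } else {
    anc <- generate_genome(spec$genome_length, mean(spec$gc_targets),
                           seed = spec$seed, bias_beta = spec$bias_beta)
    lapply(seq_len(n), function(i) {
      mutate_genome(anc, spec$divergence / 2, seed = spec$seed + i)$seq
    })
  }
  g <- as_contigs(tibble::tibble(id = ids, seq = unlist(seqs)),
                  label = "community_genomes")
  g$genus <- sprintf("Genus%02d", seq_len(n))
  g[, c("id", "genus", "seq", "length", "gc")]
}

#' Simulate a read set from a community
#'
#' Each read's source genome is drawn by abundance, its start uniformly
#' within the genome, its strand at random; platform parameters set read
#' length and per-base error. Illumina-like errors are substitutions only;
#' IonTorrent-like errors are substitutions, insertions and deletions at
#' 2:1:1 odds (flat along the read).
#'
#' @param genomes Genome tibble ([build_community()]).
#' @param n_reads Number of reads to emit.
#' @param platform `"illumina_like"` or `"iontorrent_like"`.
#' @param abundances Per-genome relative abundances (default uniform).
#' @param seed Integer seed.
#' @param error_rate Override of the platform's per-base error rate
#'   (e.g. 0 for error-free reads).
#' @return A list: `reads` (contig-style tibble) and `truth`
#'   (tibble `read_id`, `source_genome`, `start`, `strand`).
#' @export
simulate_reads <- function(genomes, n_reads,
                           platform = c("illumina_like", "iontorrent_like"),
                           abundances = rep(1 / nrow(genomes), nrow(genomes)),
                           seed = 1L, error_rate = NULL) {
  platform <- match.arg(platform)
  pp <- platform_params(platform)
  if (!is.null(error_rate)) pp$error_rate <- error_rate
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) abort_usage("n_reads must be >= 1")
  if (any(genomes$length < pp$read_length)) {
    abort_usage("read length exceeds a genome length")
  }
  withr::with_seed(seed, {
    src <- sample.int(nrow(genomes), n_reads, replace = TRUE,
                      prob = abundances)
    start <- floor(stats::runif(n_reads) *
                     (genomes$length[src] - pp$read_length + 1L)) + 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(genomes$seq[src], start, start + pp$read_length - 1L)
    flip <- strand == "-"
    if (any(flip)) {
      seqs[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
    }
    if (pp$error_rate > 0) {
      seqs <- apply_read_errors(seqs, pp$error_rate, pp$indels)
    }
    list(
      reads = as_contigs(tibble::tibble(
        id = sprintf("read_%07d", seq_len(n_reads)), seq = seqs
      ), label = paste0(platform, "_reads")),
      truth = tibble::tibble(read_id = sprintf("read_%07d", seq_len(n_reads)),
                             source_genome = genomes$id[src],
                             start = start, strand = strand)
    )
  })
}

# Per-base errors. Substitution-only: vectorised position sampling.
# With indels: per-read surgery on the (few) reads that drew errors.
apply_read_errors <- function(seqs, rate, indels) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sort(sample.int(length(chars), min(n_err[i], length(chars))))
    if (!indels) {
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(BASES, b), 1L),
                           character(1), USE.NAMES = FALSE)
    } else {
      kind <- sample(c("sub", "sub", "ins", "del"), length(pos), replace = TRUE)
      for (j in rev(seq_along(pos))) {   # right-to-left keeps positions valid
        p <- pos[j]
        chars <- switch(kind[j],
          sub = { chars[p] <- sample(setdiff(BASES, chars[p]), 1L); chars },
          ins = append(chars, sample(BASES, 1L), after = p),
          del = chars[-p]
        )
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Construct a contig set with chimera injection
#'
#' Non-chimeric contigs are verbatim slices of one genome. A chimeric
#' contig concatenates two half-length slices from two different genomes —
#' the spurious-overlap join that assembly can produce between divergent
#' bacteria. By default the two parents are drawn from compositionally
#' distant pairs (pairwise tetranucleotide-profile correlation at or below
#' the median), matching the divergent-parent character of real chimeras;
#' `distant_pairs = FALSE` draws any distinct pair. The number of chimeras
#' is exactly `round(chimera_fraction * n_total)`.
#'
#' @param genomes Genome tibble.
#' @param n_per_genome Contigs sliced per genome.
#' @param length_range Two-element bp interval for contig lengths.
#' @param chimera_fraction Fraction of all contigs replaced by chimeras.
#' @param seed Integer seed.
#' @param distant_pairs Restrict chimera parents to distant genome pairs
#'   (default `TRUE`).
#' @return A list: `contigs` (contig tibble) and `truth` (tibble
#'   `contig_id`, `source_genome`, `source_genome2`, `chimera`).
#' @export
make_contigs <- function(genomes, n_per_genome = 10L,
                         length_range = c(2000L, 10000L),
                         chimera_fraction = 0, seed = 1L,
                         distant_pairs = TRUE) {
  if (chimera_fraction < 0 || chimera_fraction > 1) {
    abort_usage("chimera_fraction must be in [0, 1]")
  }
  if (max(length_range) > min(genomes$length)) {
    abort_usage("length_range exceeds the shortest genome")
  }
  n_total <- n_per_genome * nrow(genomes)
  n_chim <- round(chimera_fraction * n_total)
  if (n_chim > 0L && nrow(genomes) < 2L) {
    abort_usage("chimeras need at least two genomes")
  }
  withr::with_seed(seed, {
    src <- rep(seq_len(nrow(genomes)), each = n_per_genome)
    lens <- length_range[1L] +
      sample.int(length_range[2L] - length_range[1L] + 1L, n_total,
                 replace = TRUE) - 1L
    slice_of <- function(gi, len) {
      s <- sample.int(genomes$length[gi] - len + 1L, 1L)
      substring(genomes$seq[gi], s, s + len - 1L)
    }
    seqs <- mapply(slice_of, src, lens)
    src2 <- rep(NA_character_, n_total)
    chim <- rep(FALSE, n_total)
    if (n_chim > 0L) {
      which_chim <- sample.int(n_total, n_chim)
      pairs <- eligible_pairs(genomes, distant_pairs)
      pick <- pairs[sample.int(nrow(pairs), n_chim, replace = TRUE), ,
                    drop = FALSE]
      for (j in seq_len(n_chim)) {
        i <- which_chim[j]
        half <- lens[i] %/% 2L
        seqs[i] <- paste0(slice_of(pick[j, 1L], half),
                          slice_of(pick[j, 2L], lens[i] - half))
        src[i] <- pick[j, 1L]
        src2[i] <- genomes$id[pick[j, 2L]]
        chim[i] <- TRUE
      }
    }
    contigs <- as_contigs(tibble::tibble(
      id = sprintf("contig_%05d", seq_len(n_total)), seq = seqs
    ), label = "simulated_contigs")
    list(contigs = contigs,
         truth = tibble::tibble(contig_id = contigs$id,
                                source_genome = genomes$id[src],
                                source_genome2 = src2,
                                chimera = chim))
  })
}

# All distinct ordered genome pairs; with distant = TRUE, only pairs whose
# canonical 4-mer profiles correlate at or below the median pairwise value.
eligible_pairs <- function(genomes, distant) {
  idx <- utils::combn(nrow(genomes), 2L)
  pairs <- cbind(idx[1L, ], idx[2L, ])
  if (distant && nrow(genomes) > 2L) {
    profs <- sapply(genomes$seq, function(s) as.numeric(kmer_profile(s, 4L)))
    cors <- apply(pairs, 1L, function(p) stats::cor(profs[, p[1L]], profs[, p[2L]]))
    pairs <- pairs[cors <= stats::median(cors), , drop = FALSE]
  }
  pairs
}

#' Build a bin fixture with known marker content
#'
#' Slices a genome into bin contigs and fabricates the marker-hit table the
#' completeness/contamination metrics consume: exactly `m_present` distinct
#' markers present, with `extra_copies` additional copies spread over
#' randomly chosen present markers. Downstream completeness is therefore
#' `100 * m_present / M` and contamination `100 * extra_copies / M` by
#' construction.
#'
#' @param genome One-row genome tibble (or a string).
#' @param bin_id Bin identifier for the emitted tables.
#' @param marker_ids Marker universe (default [default_marker_set()]).
#' @param m_present Number of distinct markers present (0..M).
#' @param extra_copies Total extra marker copies (contamination source).
#' @param n_contigs,contig_length Shape of the bin's contig set.
#' @param seed Integer seed.
#' @return A list: `contigs`, `bins` (membership tibble) and `hits`
#'   (marker-hit tibble).
#' @export
make_bin_fixture <- function(genome, bin_id = "bin_1",
                             marker_ids = default_marker_set(),
                             m_present = length(marker_ids),
                             extra_copies = 0L,
                             n_contigs = 10L, contig_length = 5000L,
                             seed = 1L) {
  if (is.data.frame(genome)) genome <- genome$seq[1L]
  M <- length(marker_ids)
  if (m_present > M) abort_usage("m_present cannot exceed the marker set size")
  if (nchar(genome) < contig_length) {
    abort_usage("genome shorter than contig_length")
  }
  withr::with_seed(seed, {
    starts <- sample.int(nchar(genome) - contig_length + 1L, n_contigs,
                         replace = TRUE)
    ids <- sprintf("%s_c%03d", bin_id, seq_len(n_contigs))
    contigs <- as_contigs(tibble::tibble(
      id = ids, seq = substring(genome, starts, starts + contig_length - 1L)
    ), label = bin_id)
    present <- if (m_present > 0L) sample(marker_ids, m_present) else character()
    copies <- stats::setNames(rep(1L, m_present), present)
    if (extra_copies > 0L && m_present > 0L) {
      bump <- sample(present, extra_copies, replace = TRUE)
      for (b in bump) copies[b] <- copies[b] + 1L
    }
    hits <- tibble::tibble(bin_id = bin_id, marker_id = present,
                           copy_count = as.integer(copies))
    list(contigs = contigs,
         bins = tibble::tibble(contig_id = ids, bin_id = bin_id),
         hits = hits)
  })
}

#' Simulate a full dataset to disk
#'
#' Runs the whole generator — genomes, reads, contigs with chimeras,
#' one bin per genome, marker hits, reference signatures — and writes
#' `genomes.fasta`, `reads.fasta`, `contigs.fasta`, `bins.tsv`,
#' `markers.tsv`, `signatures.tsv`, `read_truth.tsv` and
#' `contig_truth.tsv` under `outdir`.
#'
#' @param spec A [community_spec()].
#' @param outdir Output directory (created if needed).
#' @param n_reads Reads to simulate.
#' @param n_contigs_per_genome Contigs sliced per genome.
#' @param chimera_fraction Fraction of chimeric contigs.
#' @param k Kmer size for the signature file.
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(spec, outdir, n_reads = 20000L,
                             n_contigs_per_genome = 10L,
                             chimera_fraction = 0.1, k = 6L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genomes <- build_community(spec)
  reads <- simulate_reads(genomes, n_reads, platform = spec$platform,
                          abundances = spec$abundances, seed = spec$seed + 101L)
  ctg <- make_contigs(genomes, n_contigs_per_genome,
                      chimera_fraction = chimera_fraction,
                      seed = spec$seed + 202L)
  bins <- ctg$truth |>
    dplyr::filter(!.data$chimera) |>
    dplyr::transmute(contig_id = .data$contig_id,
                     bin_id = paste0("bin_", .data$source_genome))
  hits <- purrr::map(seq_len(nrow(genomes)), function(i) {
    make_bin_fixture(genomes[i, ], bin_id = paste0("bin_", genomes$id[i]),
                     m_present = 104L, seed = spec$seed + 300L + i)$hits
  }) |> dplyr::bind_rows()
  refs <- make_signatures(genomes, genus = genomes$genus, k = k)

  write_fasta(genomes, file.path(outdir, "genomes.fasta"))
  write_fasta(reads$reads, file.path(outdir, "reads.fasta"))
  write_fasta(ctg$contigs, file.path(outdir, "contigs.fasta"))
  write_table(bins, file.path(outdir, "bins.tsv"))
  write_table(hits, file.path(outdir, "markers.tsv"))
  write_signatures(refs, file.path(outdir, "signatures.tsv"))
  write_table(reads$truth, file.path(outdir, "read_truth.tsv"))
  write_table(ctg$truth, file.path(outdir, "contig_truth.tsv"))
  invisible(list(genomes = genomes, reads = reads, contigs = ctg,
                 bins = bins, hits = hits, refs = refs))
}
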