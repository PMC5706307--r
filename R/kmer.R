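# Canonical kmer profiles. Contig orientation is arbitrary, so every window
# is counted once as the lexicographically smaller of the kmer and its
# reverse complement; profiles therefore live on the canonical (strand-merged)
# kmer space. Windows containing N are skipped.

the <- new.env(parent = emptyenv())

# canonical representative for every kmer of size k (cached)
canonical_map <- function(k) {
  key <- paste0("k", k)
  if (is.null(the[[key]])) {
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    the[[key]] <- stats::setNames(pmin(kmers, rc), kmers)
  }
  the[[key]]
}

#' Canonical kmer frequency profile
#'
#' Pools kmer counts over one or more sequences into a single frequency
#' vector over the canonical kmer space. Each window is counted once under
#' its canonical representative, so a sequence and its reverse complement
#' yield identical profiles.
#'
#' @param seqs Character vector of sequences, or a contig tibble (its `seq`
#'   column is used).
#' @param k Kmer size, 2-8.
#' @return A named numeric vector of frequencies (summing to 1) over the
#'   canonical kmers, of class `magqc_kmer_profile`, with attributes `k` and
#'   `n_kmers_observed` (number of valid windows counted).
#' @examples
#' p <- kmer_profile("AAAA", k = 2)
#' p[p > 0]
#' attr(p, "n_kmers_observed")
#' @export
kmer_profile <- function(seqs, k) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  k <- as.integer(k)
  if (k < 2L || k > 8L) abort_usage("k must be in [2, 8]")
  seqs <- toupper(seqs)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) {
    abort_validation(paste0("no sequence of length >= k = ", k))
  }
  set <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(set, width = k,
                                                 simplify.as = "collapsed")
  canonicalize_counts(counts, k)
}

# Collapse a full 4^k count (or frequency) vector onto canonical kmers and
# normalise.
canonicalize_counts <- function(counts, k) {
  cmap <- canonical_map(k)
  canon <- rowsum(as.numeric(counts), cmap[names(counts)])
  v <- stats::setNames(as.numeric(canon), rownames(canon))
  n_obs <- sum(v)
  if (n_obs == 0) {
    abort_validation("no valid kmer window (sequences may be all N)")
  }
  structure(v / n_obs, k = k, n_kmers_observed = n_obs,
            class = "magqc_kmer_profile")
}

profile_k <- function(p) attr(p, "k")

#' Build reference signatures from genome sequences
#'
#' One canonical kmer profile per reference genome, with a genus label —
#' the composition database against which read sets, contig sets and bins
#' are profiled.
#'
#' @param genomes A contig-style tibble (`id`, `seq`) of reference genomes,
#'   one row per genome.
#' @param genus Genus label per genome (defaults to the genome id).
#' @param k Kmer size.
#' @return A tibble of class `magqc_signatures` with columns `taxon_id`,
#'   `genus` and a `profile` list-column; attribute `k`.
#' @export
make_signatures <- function(genomes, genus = genomes$id, k = 6L) {
  if (nrow(genomes) == 0L) abort_validation("at least one reference genome required")
  if (anyDuplicated(genomes$id)) abort_validation("duplicate taxon ids in references")
  out <- tibble::tibble(
    taxon_id = as.character(genomes$id),
    genus = as.character(genus),
    profile = purrr::map(genomes$seq, kmer_profile, k = k)
  )
  attr(out, "k") <- as.integer(k)
  class(out) <- c("magqc_signatures", class(out))
  out
}

#' Kmer size of a signature set
#'
#' @param refs A `magqc_signatures` tibble.
#' @return The integer kmer size the signatures were built at.
#' @export
signatures_k <- function(refs) attr(refs, "k")

# reference profiles as a (canonical kmer) x (taxon) matrix
signatures_matrix <- function(refs) {
  A <- vapply(refs$profile, as.numeric, numeric(length(refs$profile[[1L]])))
  dimnames(A) <- list(names(refs$profile[[1L]]), refs$taxon_id)
  A
}

#' Estimate taxon abundances from a kmer profile
#'
#' Models the query profile as a non-negative mixture of the reference
#' profiles and solves the non-negative least squares problem
#' `min || A x - q ||^2, x >= 0`, where the columns of `A` are the reference
#' frequency vectors. The solution is renormalised to sum to one and taxa
#' below a small floor are dropped — the alignment-free, composition-based
#' profiling strategy of FOCUS-style tools.
#'
#' @param query A `magqc_kmer_profile` (e.g. of a read set, contig set or
#'   bin), or sequences acceptable to [kmer_profile()].
#' @param refs Reference signatures ([make_signatures()] /
#'   [read_signatures()]); must share the query's kmer size.
#' @param min_abundance Floor below which taxa are dropped (default 1e-4).
#' @return A tibble `taxon_id`, `genus`, `abundance`, sorted by decreasing
#'   abundance; abundances sum to 1.
#' @export
estimate_abundances <- function(query, refs, min_abundance = 1e-4) {
  if (!inherits(query, "magqc_kmer_profile")) {
    query <- kmer_profile(query, k = signatures_k(refs))
  }
  if (!identical(profile_k(query), signatures_k(refs))) {
    abort_validation(paste0("kmer size mismatch: query k = ", profile_k(query),
                            ", references k = ", signatures_k(refs)))
  }
  A <- signatures_matrix(refs)
  fit <- pracma::lsqnonneg(A, as.numeric(query))
  x <- fit$x
  if (sum(x) <= 0) {
    return(tibble::tibble(taxon_id = character(), genus = character(),
                          abundance = numeric()))
  }
  x <- x / sum(x)
  keep <- x >= min_abundance
  x <- x[keep] / sum(x[keep])
  tibble::tibble(taxon_id = refs$taxon_id[keep],
                 genus = refs$genus[keep],
                 abundance = x) |>
    dplyr::arrange(dplyr::desc(.data$abundance))
}

#' Assign contigs to reference taxa by kmer similarity
#'
#' Computes each contig's canonical kmer profile and its Pearson correlation
#' with every reference profile; the contig is assigned to the best-matching
#' taxon if that correlation reaches `tau`, otherwise it is reported as
#' `UNASSIGNED`. Chimeric contigs blend the composition of two genomes and
#' correlate poorly with both, so they stay unassigned — the property the
#' diversity-based chimerism check relies on. Ties break toward the
#' lexicographically smaller taxon id; contigs shorter than `k` are
#' unassigned with `similarity = NA`.
#'
#' @param contigs A contig tibble.
#' @param refs Reference signatures at the assignment kmer size.
#' @param tau Minimum similarity for assignment (default 0.8).
#' @param k Kmer size (default: the reference signatures' k).
#' @return A tibble `contig_id`, `taxon_id` (or `"UNASSIGNED"`), `genus`
#'   (`NA` when unassigned), `similarity`.
#' @export
classify_contigs <- function(contigs, refs, tau = 0.8, k = signatures_k(refs)) {
  if (nrow(contigs) == 0L) abort_validation("no contigs to classify")
  if (tau < 0 || tau > 1) abort_usage("tau must be in [0, 1]")
  if (!identical(as.integer(k), signatures_k(refs))) {
    abort_validation("k must match the reference signatures' kmer size")
  }
  A <- signatures_matrix(refs)
  genus_of <- stats::setNames(refs$genus, refs$taxon_id)

  res <- purrr::map(seq_len(nrow(contigs)), function(i) {
    if (nchar(contigs$seq[i]) < k) {
      return(list(taxon_id = "UNASSIGNED", similarity = NA_real_))
    }
    p <- as.numeric(kmer_profile(contigs$seq[i], k = k))
    sims <- suppressWarnings(as.numeric(stats::cor(p, A)))
    sims[is.na(sims)] <- -Inf
    best <- order(-sims, colnames(A))[1L]
    if (is.finite(sims[best]) && sims[best] >= tau) {
      list(taxon_id = colnames(A)[best], similarity = sims[best])
    } else {
      list(taxon_id = "UNASSIGNED",
           similarity = if (is.finite(sims[best])) sims[best] else NA_real_)
    }
  })
  taxon <- vapply(res, `[[`, character(1), "taxon_id")
  tibble::tibble(
    contig_id = contigs$id,
    taxon_id = taxon,
    genus = ifelse(taxon == "UNASSIGNED", NA_character_,
                   unname(genus_of[taxon])),
    similarity = vapply(res, `[[`, numeric(1), "similarity")
  )
}
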