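# Genome relatedness: fragment-based average nucleotide identity (ANIb
# convention: 1020 bp fragments, 30% identity / 70% coverage filters) and
# tetranucleotide z-score correlation (TCS), the alignment-free complement.

#' Split a genome into ANIb fragments
#'
#' Consecutive non-overlapping windows of `fragment_len` bp; a terminal
#' remainder is kept only when it is at least 200 bp.
#'
#' @param seq A nucleotide string, or a one-row contig tibble.
#' @param fragment_len Fragment length in bp (default 1020).
#' @return A tibble `fragment_id`, `start`, `end` (1-based inclusive), `seq`.
#' @export
fragment_genome <- function(seq, fragment_len = 1020L) {
  if (is.data.frame(seq)) seq <- seq$seq[1L]
  fragment_len <- as.integer(fragment_len)
  if (fragment_len < 100L) abort_usage("fragment_len must be >= 100 bp")
  n <- nchar(seq)
  if (n < 200L) {
    abort_validation("sequence shorter than 200 bp cannot be fragmented")
  }
  starts <- seq.int(1L, n, by = fragment_len)
  ends <- pmin(starts + fragment_len - 1L, n)
  keep <- (ends - starts + 1L) == fragment_len | (ends - starts + 1L) >= 200L
  starts <- starts[keep]; ends <- ends[keep]
  tibble::tibble(
    fragment_id = sprintf("frag_%05d", seq_along(starts)),
    start = starts,
    end = ends,
    seq = substring(seq, starts, ends)
  )
}

# Seed-and-extend alignment of query fragments against a subject strand.
# All 15-mer seeds (one per 15 bp stride) of all fragments are matched
# exactly against the subject in one pass; each fragment votes for the
# subject diagonal with most seed hits and is scored by gap-free base
# identity on that diagonal. Returns per-fragment identity and coverage.
align_fragments_strand <- function(frags, subject_seq, seed_len = 15L) {
  subject <- Biostrings::DNAString(subject_seq)
  slen <- nchar(subject_seq)
  n_seeds_per <- (nchar(frags$seq) - seed_len) %/% seed_len + 1L
  fi <- rep.int(seq_len(nrow(frags)), n_seeds_per)
  off <- unlist(lapply(n_seeds_per, function(m)
    seq.int(1L, by = seed_len, length.out = m)), use.names = FALSE)
  seed <- substring(frags$seq[fi], off, off + seed_len - 1L)
  ok <- !grepl("N", seed, fixed = TRUE)
  fi <- fi[ok]; off <- off[ok]; seed <- seed[ok]
  empty <- tibble::tibble(fi = integer(), identity = numeric(),
                          coverage = numeric())
  if (length(seed) == 0L) return(empty)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed))
  starts <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
  n_hits <- lengths(starts)
  if (sum(n_hits) == 0L) return(empty)
  hit_fi <- rep.int(fi, n_hits)
  hit_diag <- unlist(starts, use.names = FALSE) - rep.int(off, n_hits) + 1L
  # modal diagonal per fragment
  key <- paste0(hit_fi, ":", hit_diag)
  votes <- table(key)
  split_votes <- split(votes, sub(":.*$", "", names(votes)))
  best <- vapply(split_votes, function(v) names(v)[which.max(v)], character(1))
  bfi <- as.integer(sub(":.*$", "", best))
  bdiag <- as.integer(sub("^.*:", "", best))
  flen <- nchar(frags$seq[bfi])
  s0 <- pmax(bdiag, 1L)
  s1 <- pmin(bdiag + flen - 1L, slen)
  valid <- s1 >= s0
  q0 <- s0 - bdiag + 1L
  q1 <- s1 - bdiag + 1L
  qs <- substring(frags$seq[bfi], q0, q1)
  ss <- substring(subject_seq, s0, s1)
  matches <- vapply(seq_along(qs), function(i) {
    if (!valid[i]) return(0L)
    sum(charToRaw(qs[i]) == charToRaw(ss[i]))
  }, integer(1))
  overlap <- ifelse(valid, s1 - s0 + 1L, 1L)
  tibble::tibble(fi = bfi,
                 identity = ifelse(valid, matches / overlap, 0),
                 coverage = ifelse(valid, overlap / flen, 0))
}

#' Fragment-based average nucleotide identity (ANIb)
#'
#' The query genome is cut into fragments ([fragment_genome()]) and each
#' fragment is locally aligned against the subject on both strands by exact
#' 15-mer seeding and gap-free extension along the best-supported diagonal.
#' A fragment contributes iff its identity is at least `ani_min_identity`
#' over at least `ani_min_coverage` of its length; ANI is the mean identity
#' (percent) over contributing fragments. Two genomes are called the same
#' species when ANI exceeds `species_ani_threshold` (strictly greater than,
#' default 95%).
#'
#' @param query,subject Nucleotide strings or one-row contig tibbles.
#' @param config A [magqc_config()] (fragment length and filters).
#' @return An object of class `magqc_ani`; `glance()` gives the one-row
#'   summary (`ani`, `n_fragments`, `n_fragments_aligned`,
#'   `aligned_fraction`, `same_species`), `tidy()` the per-fragment table.
#' @examples
#' g <- generate_genome(5000, gc = 0.5, seed = 1)
#' glance(anib(g, g, magqc_config(ani_fragment_len = 500)))
#' @export
anib <- function(query, subject, config = magqc_config()) {
  if (is.data.frame(query)) query <- query$seq[1L]
  if (is.data.frame(subject)) subject <- subject$seq[1L]
  flen <- config$ani_fragment_len
  if (nchar(query) < flen || nchar(subject) < flen) {
    abort_validation(paste0("both genomes must be at least one fragment (",
                            flen, " bp) long"))
  }
  frags <- fragment_genome(query, flen)
  fwd <- align_fragments_strand(frags, subject)
  rev <- align_fragments_strand(
    frags, as.character(Biostrings::reverseComplement(Biostrings::DNAString(subject)))
  )
  per_frag <- dplyr::bind_rows(fwd, rev) |>
    dplyr::group_by(.data$fi) |>
    dplyr::slice_max(.data$identity * .data$coverage, n = 1L,
                     with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::right_join(tibble::tibble(fi = seq_len(nrow(frags))), by = "fi") |>
    dplyr::arrange(.data$fi) |>
    dplyr::mutate(
      fragment_id = frags$fragment_id[.data$fi],
      identity = dplyr::coalesce(.data$identity, 0),
      coverage = dplyr::coalesce(.data$coverage, 0),
      passed = .data$identity >= config$ani_min_identity &
        .data$coverage >= config$ani_min_coverage
    ) |>
    dplyr::select("fragment_id", "identity", "coverage", "passed")
  n_aligned <- sum(per_frag$passed)
  ani <- if (n_aligned == 0L) NA_real_ else
    100 * mean(per_frag$identity[per_frag$passed])
  structure(list(
    ani = ani,
    n_fragments = nrow(frags),
    n_fragments_aligned = n_aligned,
    aligned_fraction = n_aligned / nrow(frags),
    same_species = !is.na(ani) && ani > config$species_ani_threshold,
    per_fragment = per_frag,
    species_ani_threshold = config$species_ani_threshold
  ), class = "magqc_ani")
}

#' @export
print.magqc_ani <- function(x, ...) {
  cat(sprintf(
    "<magqc_ani> ANI %s over %d/%d fragments (aligned fraction %.2f); same species: %s\n",
    ifelse(is.na(x$ani), "undefined", sprintf("%.2f%%", x$ani)),
    x$n_fragments_aligned, x$n_fragments, x$aligned_fraction, x$same_species))
  invisible(x)
}

#' @rdname anib
#' @param x A `magqc_ani` object.
#' @param ... Unused.
#' @export
tidy.magqc_ani <- function(x, ...) x$per_fragment

#' @rdname anib
#' @export
glance.magqc_ani <- function(x, ...) {
  tibble::tibble(ani = x$ani, n_fragments = x$n_fragments,
                 n_fragments_aligned = x$n_fragments_aligned,
                 aligned_fraction = x$aligned_fraction,
                 same_species = x$same_species)
}

#' Tetranucleotide z-scores
#'
#' Strand-merged observed tetranucleotide counts are compared with the
#' expectation under the maximal-order Markov model,
#' `exp(w1w2w3w4) = n(w1w2w3) * n(w2w3w4) / n(w2w3)`, with variance
#' `exp * (1 - n(w1w2w3)/n(w2w3)) * (1 - n(w2w3w4)/n(w2w3))`;
#' `z = (obs - exp) / sqrt(var)`. Entries with zero expectation or variance
#' are set to 0. Strand merging (counting the sequence plus its reverse
#' complement) makes `z` identical for a genome and its reverse complement.
#'
#' @param seq Nucleotide string or one-row contig tibble.
#' @param min_len Minimum length (default 5000; z-scores are unstable on
#'   shorter sequences).
#' @return Named numeric vector of 256 z-scores, class `magqc_tetra`.
#' @export
tetra_zscores <- function(seq, min_len = 5000L) {
  if (is.data.frame(seq)) seq <- seq$seq[1L]
  if (nchar(seq) < min_len) {
    abort_validation(paste0("sequence shorter than ", min_len,
                            " bp; tetranucleotide z-scores unstable"))
  }
  x <- Biostrings::DNAString(seq)
  xr <- Biostrings::reverseComplement(x)
  cnt <- function(w) {
    raw <- Biostrings::oligonucleotideFrequency(x, w) +
      Biostrings::oligonucleotideFrequency(xr, w)
    stats::setNames(as.numeric(raw), names(raw))  # double: products overflow int
  }
  n4 <- cnt(4L); n3 <- cnt(3L); n2 <- cnt(2L)
  kmers <- names(n4)
  left <- substr(kmers, 1L, 3L)     # w1w2w3
  right <- substr(kmers, 2L, 4L)    # w2w3w4
  mid <- substr(kmers, 2L, 3L)      # w2w3
  nl <- n3[left]; nr <- n3[right]; nm <- n2[mid]
  exp4 <- ifelse(nm > 0, nl * nr / nm, 0)
  varr <- ifelse(nm > 0, exp4 * (1 - nl / nm) * (1 - nr / nm), 0)
  z <- ifelse(varr > 0, (n4 - exp4) / sqrt(varr), 0)
  structure(stats::setNames(as.numeric(z), kmers), class = "magqc_tetra")
}

#' Tetranucleotide correlation (TCS)
#'
#' Pearson correlation between two tetranucleotide z-score vectors; the
#' alignment-free relatedness score used alongside ANI. Values are
#' comparable only within this implementation's z-score convention.
#'
#' @param a,b `magqc_tetra` vectors ([tetra_zscores()]), or sequences.
#' @return Correlation in `[-1, 1]`; `NA` if either vector has zero
#'   variance.
#' @export
tcs <- function(a, b) {
  if (!inherits(a, "magqc_tetra")) a <- tetra_zscores(a)
  if (!inherits(b, "magqc_tetra")) b <- tetra_zscores(b)
  if (length(a) != 256L || length(b) != 256L) {
    abort_validation("tetranucleotide z-score vectors must have length 256")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.numeric(a), as.numeric(b))
}

#' Relate two genomes by ANI and TCS
#'
#' Convenience wrapper combining [anib()] and [tcs()] into the one-row
#' relatedness report the `relate` stage emits.
#'
#' @inheritParams anib
#' @return One-row tibble: `ani`, `aligned_fraction`, `tcs`, `same_species`.
#' @export
relate_genomes <- function(query, subject, config = magqc_config()) {
  a <- anib(query, subject, config)
  tibble::tibble(
    ani = a$ani,
    aligned_fraction = a$aligned_fraction,
    tcs = tcs(query, subject),
    same_species = a$same_species
  )
}
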