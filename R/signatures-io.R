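# Reference signature TSV: taxon_id, genus, then one column per kmer of the
# full 4^k space. Profiles are canonical (strand-merged), so the mass of a
# kmer pair sits on its lexicographically smaller member and the reverse
# complement column is zero; rows sum to 1 either way.

#' Write reference signatures to TSV
#'
#' @param refs Signatures from [make_signatures()], or a genome tibble
#'   (`id`, `seq`), in which case signatures are built first.
#' @param path Output TSV path.
#' @param k Kmer size, used only when `refs` is a genome tibble.
#' @param genus Genus labels, used only when `refs` is a genome tibble.
#' @return The signatures, invisibly.
#' @export
write_signatures <- function(refs, path, k = 6L, genus = NULL) {
  if (!inherits(refs, "magqc_signatures")) {
    refs <- make_signatures(refs, genus = genus %||% refs$id, k = k)
  }
  k <- signatures_k(refs)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  cmap <- canonical_map(k)
  wide <- vapply(refs$profile, function(p) {
    full <- stats::setNames(numeric(length(kmers)), kmers)
    full[names(p)] <- as.numeric(p)
    full
  }, numeric(length(kmers)))
  tab <- dplyr::bind_cols(
    tibble::tibble(taxon_id = refs$taxon_id, genus = refs$genus),
    tibble::as_tibble(t(wide))
  )
  write_table(tab, path)
  invisible(refs)
}

#' Read reference signatures from TSV
#'
#' Infers k from the number of kmer columns and collapses frequencies onto
#' the canonical kmer space, so `read_signatures(write_signatures(x))`
#' reproduces `x` exactly.
#'
#' @param path Path to a signatures TSV.
#' @return A `magqc_signatures` tibble.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    taxon_id = readr::col_character(), genus = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("taxon_id", "genus") %in% names(tab))) {
    abort_format("signature TSV must start with columns taxon_id, genus")
  }
  kcols <- setdiff(names(tab), c("taxon_id", "genus"))
  k <- as.integer(round(log(length(kcols), base = 4)))
  if (4^k != length(kcols) || !setequal(kcols, Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))) {
    abort_format("signature TSV kmer columns do not span a full 4^k kmer space")
  }
  out <- tibble::tibble(
    taxon_id = tab$taxon_id,
    genus = tab$genus,
    profile = purrr::map(seq_len(nrow(tab)), function(i) {
      v <- as.numeric(tab[i, kcols])
      names(v) <- kcols
      canonicalize_counts(v, k)
    })
  )
  attr(out, "k") <- k
  class(out) <- c("magqc_signatures", class(out))
  out
}
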