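# Canonical kmer profiles, NNLS mixture estimation, per-contig assignment.

test_that("kmer_profile counts canonical windows and skips N", {
  p <- kmer_profile("AAAA", k = 2)
  expect_equal(unname(p[["AA"]]), 1)
  expect_equal(attr(p, "n_kmers_observed"), 3)

  # N windows skipped: ACNGT has windows AC, CN, NG, GT -> AC and GT only,
  # and GT canonicalises to AC, so all retained mass sits on AC
  pn <- kmer_profile("ACNGT", k = 2)
  expect_equal(attr(pn, "n_kmers_observed"), 2)
  expect_equal(unname(pn[["AC"]]), 1.0)

  expect_error(kmer_profile("A", k = 2), class = "magqc_validation_error")
  expect_error(kmer_profile("ACGT", k = 1), class = "magqc_usage_error")
})

test_that("kmer_profile is strand-symmetric", {
  withr::local_seed(8)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    expect_equal(as.numeric(kmer_profile(s, 4)),
                 as.numeric(kmer_profile(rc(s), 4)))
  }
  expect_equal(sum(kmer_profile("ACGTACGTTG", 3)), 1)
})

test_that("estimate_abundances recovers pure and convex mixtures", {
  comm <- test_community()
  refs <- comm$refs6

  pure <- estimate_abundances(refs$profile[[3]], refs)
  expect_equal(pure$taxon_id[1], "genome_03")
  expect_equal(pure$abundance[1], 1.0, tolerance = 1e-9)

  q <- refs$profile[[1]]
  mix <- 0.7 * as.numeric(refs$profile[[1]]) + 0.3 * as.numeric(refs$profile[[2]])
  qmix <- structure(stats::setNames(mix, names(refs$profile[[1]])),
                    k = 6L, class = "magqc_kmer_profile")
  est <- estimate_abundances(qmix, refs)
  expect_equal(sum(est$abundance), 1, tolerance = 1e-9)
  expect_equal(est$abundance[est$taxon_id == "genome_01"], 0.7,
               tolerance = 1e-6)
  expect_equal(est$abundance[est$taxon_id == "genome_02"], 0.3,
               tolerance = 1e-6)

  expect_error(estimate_abundances(kmer_profile("ACGTACGT", 4), refs),
               "mismatch", class = "magqc_validation_error")
})

test_that("NNLS solution matches exhaustive active-set enumeration", {
  withr::local_seed(31)
  for (i in 1:20) {
    A <- matrix(runif(15), 5, 3)
    b <- runif(5)
    ours <- pracma::lsqnonneg(A, b)$x
    oracle <- oracle_nnls(A, b)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
  # a zero-weight reference stays absent after renormalisation
  A <- matrix(runif(30), 10, 3)
  truth <- c(0.6, 0.4, 0)
  b <- as.numeric(A %*% truth)
  x <- pracma::lsqnonneg(A, b)$x
  expect_equal(x / sum(x), truth, tolerance = 1e-8)
})

test_that("classify_contigs assigns verbatim slices and respects tau", {
  comm <- test_community()
  made <- make_contigs(comm$genomes, n_per_genome = 3,
                       length_range = c(5000, 10000), seed = 13)
  asn <- classify_contigs(made$contigs, comm$refs4, tau = 0.8)
  joined <- dplyr::left_join(asn, made$truth, by = "contig_id")
  expect_true(all(joined$taxon_id == joined$source_genome))

  # tau = 1 forces UNASSIGNED for any non-identical profile
  strict <- classify_contigs(made$contigs[1, ], comm$refs4, tau = 1.0)
  expect_equal(strict$taxon_id, "UNASSIGNED")

  # a contig shorter than k is unassigned with similarity not computed
  short <- as_contigs(tibble::tibble(id = "s", seq = "ACG"))
  out <- classify_contigs(short, comm$refs4, tau = 0)
  expect_equal(out$taxon_id, "UNASSIGNED")
  expect_true(is.na(out$similarity))
})

test_that("lowering tau never decreases the number of assigned contigs", {
  comm <- test_community()
  made <- make_contigs(comm$genomes, n_per_genome = 2,
                       chimera_fraction = 0.3, seed = 21)
  taus <- c(1, 0.95, 0.9, 0.8, 0.5, 0)
  n_assigned <- vapply(taus, function(t) {
    sum(classify_contigs(made$contigs, comm$refs4, tau = t)$taxon_id !=
          "UNASSIGNED")
  }, numeric(1))
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("signature TSV round-trips profiles exactly", {
  comm <- test_community()
  g3 <- comm$genomes[1:3, ]
  refs <- make_signatures(g3, genus = g3$genus, k = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(refs, f)

  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_equal(ncol(tab), 2L + 256L)
  freq <- as.matrix(tab[, -(1:2)])
  expect_equal(unname(rowSums(freq)), rep(1, 3), tolerance = 1e-9)

  back <- read_signatures(f)
  expect_equal(back$taxon_id, refs$taxon_id)
  expect_equal(back$genus, refs$genus)
  for (i in 1:3) {
    expect_equal(as.numeric(back$profile[[i]]),
                 as.numeric(refs$profile[[i]]), tolerance = 1e-12)
  }
})
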