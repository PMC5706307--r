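# Bin quality: GC statistics, genus tables, marker completeness/contamination.

test_that("gc_content follows the N-exclusion rule", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("ATGN"), 100 / 3)
  expect_true(is.na(gc_content("NNNN")))
  expect_equal(gc_content("atgc"), 50)   # case-insensitive
})

test_that("bin_gc_stats uses the sample standard deviation", {
  mk <- function(gcs) {
    as_contigs(tibble::tibble(
      id = paste0("c", seq_along(gcs)),
      seq = vapply(gcs, function(g) {
        paste0(strrep("G", g), strrep("A", 100 - g))
      }, character(1))
    ))
  }
  st <- bin_gc_stats(mk(c(40, 50, 60)))
  expect_equal(st$gc_mean, 50)
  expect_equal(st$gc_sd, 10)

  expect_equal(bin_gc_stats(mk(55))$gc_sd, 0)

  dup <- bin_gc_stats(mk(c(40, 50, 60, 40, 50, 60)))
  expect_equal(dup$gc_mean, 50)
  # reordering leaves the statistics unchanged
  expect_equal(bin_gc_stats(mk(c(60, 40, 50))), st)
})

test_that("bin_taxon_table tallies genera and unassigned mass per bin", {
  asn <- tibble::tibble(contig_id = paste0("c", 1:4),
                        genus = c("X", "X", "Y", NA))
  bins <- tibble::tibble(contig_id = paste0("c", 1:4), bin_id = "b1")
  tab <- bin_taxon_table(asn, bins)
  expect_equal(tab$count[tab$genus == "X"], 2L)
  expect_equal(tab$count[tab$genus == "Y"], 1L)
  expect_equal(tab$count[tab$genus == "UNASSIGNED"], 1L)

  # genus richness via the diversity module: {X:2, Y:1} -> 1/ln 3
  counts <- tab$count[tab$genus != "UNASSIGNED"]
  expect_equal(diversity_indices(counts)$margalef_d, 1 / log(3),
               tolerance = 1e-9)
})

test_that("completeness and contamination follow the marker formulas", {
  M <- default_marker_set()
  mk <- function(markers, copies = 1L) {
    tibble::tibble(bin_id = "b", marker_id = markers,
                   copy_count = rep_len(copies, length(markers)))
  }
  full <- completeness_contamination(mk(M), M)
  expect_equal(full$completeness, 100)
  expect_equal(full$contamination, 0)

  half <- completeness_contamination(mk(M[1:52]), M)
  expect_equal(half$completeness, 50)

  tri <- mk(M)
  tri$copy_count[1] <- 3L
  cc <- completeness_contamination(tri, M)
  expect_equal(cc$completeness, 100)
  expect_equal(cc$contamination, 100 * 2 / 104)

  expect_error(completeness_contamination(mk("not_a_marker"), M),
               class = "magqc_validation_error")
  none <- completeness_contamination(mk(M[1]), M, bin_ids = c("b", "empty"))
  expect_equal(none$completeness[none$bin_id == "empty"], 0)
})

test_that("completeness is monotone as hits accumulate", {
  M <- default_marker_set()
  withr::local_seed(17)
  order_ids <- sample(M)
  comp <- vapply(c(1, 10, 52, 80, 104), function(m) {
    completeness_contamination(
      tibble::tibble(bin_id = "b", marker_id = order_ids[1:m],
                     copy_count = 1L), M)$completeness
  }, numeric(1))
  expect_true(all(diff(comp) > 0))
  expect_equal(comp[3], 50)
})

test_that("synthetic bin fixtures hit their completeness targets exactly", {
  comm <- test_community()
  grid <- list(c(104, 0), c(52, 0), c(104, 2), c(30, 5))
  for (gr in grid) {
    fx <- make_bin_fixture(comm$genomes[1, ], m_present = gr[1],
                           extra_copies = gr[2], seed = gr[1] + gr[2])
    cc <- completeness_contamination(fx$hits)
    expect_equal(cc$completeness, 100 * gr[1] / 104)
    expect_equal(cc$contamination, 100 * gr[2] / 104)
  }
})

test_that("bin_quality joins contig, taxon and marker views", {
  comm <- test_community()
  made <- make_contigs(comm$genomes[1:3, ], n_per_genome = 4,
                       length_range = c(4000, 8000), seed = 33,
                       distant_pairs = FALSE)
  bins <- dplyr::transmute(made$truth, contig_id = contig_id,
                           bin_id = paste0("bin_", source_genome))
  asn <- classify_contigs(made$contigs, comm$refs4, tau = 0.8)
  hits <- dplyr::bind_rows(lapply(1:3, function(i) {
    make_bin_fixture(comm$genomes[i, ],
                     bin_id = paste0("bin_", comm$genomes$id[i]),
                     m_present = 52, seed = i)$hits
  }))
  q <- bin_quality(made$contigs, bins, asn, hits = hits)
  expect_equal(nrow(q), 3L)
  expect_equal(sort(q$bin_id), sort(unique(bins$bin_id)))
  expect_true(all(q$completeness == 50))
  expect_true(all(q$dominant_share > 0.9))
  expect_true(all(q$genus_count == 1L))
  expect_true(all(q$gc_sd >= 0))
  # one bin per genome, dominant genus equals the source genus
  expect_setequal(q$dominant_genus, comm$genomes$genus[1:3])

  expect_error(bin_quality(made$contigs[-1, ], bins, asn),
               class = "magqc_validation_error")
})
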