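# The seeded community generator.

test_that("generate_genome hits its GC target and is reproducible", {
  g <- generate_genome(1e5, 0.6, seed = 1)
  gcobs <- gc_content(g) / 100
  expect_gt(gcobs, 0.59)   # binomial 99.99% interval at n = 1e5
  expect_lt(gcobs, 0.61)
  expect_identical(generate_genome(1e5, 0.6, seed = 1), g)
  expect_false(identical(generate_genome(1e5, 0.6, seed = 2), g))
  expect_error(generate_genome(1e5, 0, seed = 1), class = "magqc_usage_error")
  expect_error(generate_genome(500, 0.5, seed = 1), class = "magqc_usage_error")
})

test_that("mutate_genome edits at the requested rate with a faithful edit list", {
  g <- generate_genome(1e6, 0.5, seed = 2)
  same <- mutate_genome(g, 0, seed = 3)
  expect_identical(same$seq, g)
  expect_equal(nrow(same$edits), 0L)

  mut <- mutate_genome(g, 0.02, seed = 4)
  expect_gt(nrow(mut$edits), 19400)   # binomial interval at n = 1e6
  expect_lt(nrow(mut$edits), 20600)
  # edit list is exact: mismatch positions are precisely the edits
  a <- charToRaw(g); b <- charToRaw(mut$seq)
  expect_identical(which(a != b), as.integer(mut$edits$pos))
  expect_true(all(mut$edits$ref != mut$edits$alt))
})

test_that("simulate_reads respects counts, abundances and error-free extraction", {
  comm <- test_community()
  g2 <- comm$genomes[1:2, ]
  sim <- simulate_reads(g2, 1000, abundances = c(0.5, 0.5), seed = 5)
  expect_equal(nrow(sim$reads), 1000L)
  expect_true(all(sim$reads$length == 250L))

  # error 0: every read is an exact (possibly reverse-complemented) substring
  clean <- simulate_reads(g2, 50, seed = 6, error_rate = 0)
  src <- clean$truth
  for (i in seq_len(50)) {
    gseq <- g2$seq[g2$id == src$source_genome[i]]
    expected <- substr(gseq, src$start[i], src$start[i] + 249L)
    if (src$strand[i] == "-") expected <- rc(expected)
    expect_identical(clean$reads$seq[i], expected)
  }

  skewed <- simulate_reads(g2, 1e4, abundances = c(0.9, 0.1), seed = 7)
  n1 <- sum(skewed$truth$source_genome == "genome_01")
  expect_gt(n1, 9000 - 3 * sqrt(1e4 * 0.09))
  expect_lt(n1, 9000 + 3 * sqrt(1e4 * 0.09))

  noisy <- simulate_reads(g2, 200, platform = "iontorrent_like", seed = 8)
  expect_true(any(noisy$reads$length != 200L))   # indels change lengths
  expect_error(simulate_reads(g2, 0, seed = 1), class = "magqc_usage_error")
})

test_that("make_contigs injects the exact chimera count with truthful flags", {
  comm <- test_community()
  none <- make_contigs(comm$genomes, n_per_genome = 3, chimera_fraction = 0,
                       seed = 11)
  expect_false(any(none$truth$chimera))

  some <- make_contigs(comm$genomes, n_per_genome = 10,
                       chimera_fraction = 0.2, seed = 12)
  expect_equal(sum(some$truth$chimera), 20L)
  expect_true(all(is.na(some$truth$source_genome2[!some$truth$chimera])))
  expect_true(all(some$truth$source_genome2[some$truth$chimera] !=
                    some$truth$source_genome[some$truth$chimera]))

  # verbatim slices: non-chimeric contigs occur in their source genome
  idx <- which(!some$truth$chimera)[1:5]
  for (i in idx) {
    gseq <- comm$genomes$seq[comm$genomes$id == some$truth$source_genome[i]]
    expect_true(grepl(some$contigs$seq[i], gseq, fixed = TRUE))
  }

  again <- make_contigs(comm$genomes, n_per_genome = 10,
                        chimera_fraction = 0.2, seed = 12)
  expect_identical(again$contigs$seq, some$contigs$seq)
  expect_error(make_contigs(comm$genomes, length_range = c(1e6, 2e6)),
               class = "magqc_usage_error")
})

test_that("simulate_dataset writes a complete, reloadable file set", {
  spec <- community_spec(n_genomes = 3, genome_length = 2e4, seed = 77)
  outdir <- withr::local_tempdir()
  sim <- simulate_dataset(spec, outdir, n_reads = 200,
                          n_contigs_per_genome = 4, chimera_fraction = 0.25,
                          k = 4)
  files <- c("genomes.fasta", "reads.fasta", "contigs.fasta", "bins.tsv",
             "markers.tsv", "signatures.tsv", "read_truth.tsv",
             "contig_truth.tsv")
  for (f in files) expect_true(file.exists(file.path(outdir, f)))
  expect_equal(nrow(read_fasta(file.path(outdir, "reads.fasta"))), 200L)
  refs <- read_signatures(file.path(outdir, "signatures.tsv"))
  expect_equal(nrow(refs), 3L)
  hits <- read_marker_hits(file.path(outdir, "markers.tsv"))
  expect_equal(dplyr::n_distinct(hits$bin_id), 3L)
})
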