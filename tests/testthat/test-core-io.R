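# FASTA/SAM/TSV ingestion and validation.

write_tmp <- function(lines, ext = ".fasta") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_fasta parses records, concatenates lines and uppercases", {
  f <- write_tmp(c(">c1", "ACGT"))
  ctg <- read_fasta(f)
  expect_equal(nrow(ctg), 1L)
  expect_equal(ctg$length, 4L)

  f2 <- write_tmp(c(">c1", "AC", "GT", ">c2", "GG"))
  ctg2 <- read_fasta(f2)
  expect_equal(ctg2$seq, c("ACGT", "GG"))
  expect_equal(ctg2$length, c(4L, 2L))

  f3 <- write_tmp(c(">c1 description here", "acgtn"))
  ctg3 <- read_fasta(f3)
  expect_equal(ctg3$id, "c1")
  expect_equal(ctg3$seq, "ACGTN")
})

test_that("read_fasta rejects duplicates, bad alphabet and malformed files", {
  f <- write_tmp(c(">c1", "ACGT", ">c1", "GG"))
  expect_error(read_fasta(f), "duplicate", class = "magqc_validation_error")

  f2 <- write_tmp(c(">c1", "ACXT"))
  err <- expect_error(read_fasta(f2), class = "magqc_validation_error")
  expect_match(conditionMessage(err), "position 3")
  expect_match(conditionMessage(err), "c1")

  f3 <- write_tmp(c("ACGT", ">c1"))
  expect_error(read_fasta(f3), "line 1", class = "magqc_format_error")
  f4 <- write_tmp(character(0))
  expect_error(read_fasta(f4), class = "magqc_format_error")
})

test_that("FASTA round-trip preserves ids, order and sequences", {
  comm <- test_community()
  contigs <- make_contigs(comm$genomes, n_per_genome = 2, seed = 9)$contigs
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(contigs, f)
  back <- read_fasta(f)
  expect_equal(back$id, contigs$id)
  expect_equal(back$seq, contigs$seq)
})

test_that("read_mapping handles TSV pairs, de-duplication and total_reads", {
  f <- write_tmp(c("r1\tc1", "r2\tc1", "r3\tc2"), ext = ".tsv")
  mp <- read_mapping(f, total_reads = 4)
  expect_equal(nrow(mp), 3L)
  expect_equal(total_reads(mp), 4L)

  fdup <- write_tmp(c("r1\tc1", "r1\tc1"), ext = ".tsv")
  expect_equal(nrow(read_mapping(fdup)), 1L)

  expect_error(read_mapping(f, total_reads = 2),
               class = "magqc_validation_error")
})

test_that("read_mapping honours SAM flags for unmapped and secondary records", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:1000",
    "r1\t0\tc1\t1\t60\t50M\t*\t0\t0\tACGT\t*",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",        # unmapped
    "r3\t256\tc1\t5\t0\t50M\t*\t0\t0\tACGT\t*",   # secondary
    "r4\t2048\tc1\t9\t0\t50M\t*\t0\t0\tACGT\t*",  # supplementary
    "r5\t16\tc1\t9\t60\t50M\t*\t0\t0\tACGT\t*"    # reverse strand, kept
  )
  f <- write_tmp(sam, ext = ".sam")
  mp <- read_mapping(f, total_reads = 5)
  expect_setequal(mp$read_id, c("r1", "r5"))

  # headerless SAM works too
  f2 <- write_tmp(sam[-(1:2)], ext = ".sam")
  expect_equal(nrow(read_mapping(f2)), 2L)
})

test_that("write_table emits header-first TSV in input order and round-trips", {
  rows <- tibble::tibble(a = c("x", "y"), b = 1:2, c = c(0.5, 1.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(rows, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)
  expect_equal(lines[1], "a\tb\tc")
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rows))

  empty <- rows[0, ]
  write_table(empty, f)
  expect_equal(readLines(f), "a\tb\tc")
})

test_that("config validates ranges and reads YAML with overrides", {
  expect_error(magqc_config(mag_dominance = 1.2), class = "magqc_usage_error")
  expect_error(magqc_config(kmer_size_profile = 9), class = "magqc_usage_error")
  expect_error(magqc_config(ani_fragment_len = 50), class = "magqc_usage_error")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mag_dominance: 0.9", "bootstrap_B: 500"), f)
  cfg <- read_config(f, novel_min_completeness = 60)
  expect_equal(cfg$mag_dominance, 0.9)
  expect_equal(cfg$bootstrap_B, 500L)
  expect_equal(cfg$novel_min_completeness, 60)
  writeLines("not_a_key: 1", f)
  expect_error(read_config(f), "unknown config key",
               class = "magqc_usage_error")
})
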