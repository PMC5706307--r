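# Diversity indices and the bootstrap chimerism contrast.

test_that("diversity indices match closed forms", {
  u <- diversity_indices(c(25, 25, 25, 25))
  expect_equal(u$shannon_h, log(4), tolerance = 1e-9)
  expect_equal(u$pielou_j, 1, tolerance = 1e-9)
  expect_equal(u$simpson_1minusD, 0.75, tolerance = 1e-9)

  m <- diversity_indices(rep(20, 5))   # S = 5, N = 100
  expect_equal(m$margalef_d, 4 / log(100), tolerance = 1e-9)

  s <- diversity_indices(c(7))
  expect_equal(s$margalef_d, 0)
  expect_equal(s$shannon_h, 0)
  expect_true(is.na(s$pielou_j))
  expect_equal(s$simpson_1minusD, 0)

  expect_error(diversity_indices(c(0, 0)), class = "magqc_validation_error")
  expect_error(diversity_indices(c(-1, 2)), class = "magqc_validation_error")
})

test_that("diversity matches a direct per-item oracle and vegan on random tables", {
  withr::local_seed(202)
  has_vegan <- requireNamespace("vegan", quietly = TRUE)
  for (i in 1:200) {
    counts <- rpois(sample.int(30, 1) + 1, lambda = sample.int(50, 1))
    if (sum(counts) == 0) counts <- counts + 1
    d <- diversity_indices(counts)
    oc <- oracle_diversity(counts)
    expect_equal(d$margalef_d, oc$margalef, tolerance = 1e-12)
    expect_equal(d$shannon_h, oc$shannon, tolerance = 1e-12)
    expect_equal(d$pielou_j, oc$pielou, tolerance = 1e-12)
    expect_equal(d$simpson_1minusD, oc$simpson_c, tolerance = 1e-12)
    if (has_vegan && sum(counts > 0) > 0) {
      expect_equal(d$shannon_h, unname(vegan::diversity(counts)),
                   tolerance = 1e-12)
      expect_equal(d$simpson_1minusD,
                   unname(vegan::diversity(counts, index = "simpson")),
                   tolerance = 1e-12)
    }
  }
})

test_that("log_base override rescales Margalef and Shannon consistently", {
  d2 <- diversity_indices(c(10, 20, 30), log_base = 2)
  dn <- diversity_indices(c(10, 20, 30))
  expect_equal(d2$shannon_h, dn$shannon_h / log(2), tolerance = 1e-12)
  expect_equal(d2$pielou_j, dn$pielou_j, tolerance = 1e-12)
})

test_that("identical profiles give zero deltas and no flag", {
  x <- c(a = 100, b = 200, c = 300)
  rep <- assess_chimerism(x, x, B = 200, seed = 4)
  expect_equal(rep$delta_richness, 0)
  expect_equal(rep$delta_evenness, 0)
  expect_false(rep$chimerism_flag)
  expect_true(rep$ci_low <= 0 && rep$ci_high >= 0)
})

test_that("taxon loss is flagged; evenness gain alone is not", {
  withr::local_seed(11)
  p <- rlnorm(10, sdlog = 0.5); p <- p / sum(p)
  reads <- round(1e4 * p)
  # drop 3 of 10 taxa, redistribute counts to keep N comparable
  contigs <- reads
  contigs[1:3] <- 0
  contigs <- round(contigs / sum(contigs) * sum(reads))
  rep <- assess_chimerism(reads, contigs[contigs > 0], B = 1000, seed = 2)
  expect_lt(rep$delta_richness, 0)
  expect_true(rep$chimerism_flag)
  # point delta equals the direct index computation on both tables
  expect_equal(rep$delta_richness,
               diversity_indices(contigs[contigs > 0])$margalef_d -
                 diversity_indices(reads)$margalef_d, tolerance = 1e-12)

  evened <- rep(round(sum(reads) / 10), 10)
  rep2 <- assess_chimerism(reads, evened, B = 1000, seed = 3)
  expect_gt(rep2$delta_evenness, 0)
  expect_false(rep2$chimerism_flag)
})

test_that("the chimerism report is reproducible and validates B", {
  x <- c(50, 60, 70, 80)
  y <- c(40, 70, 60, 90)
  a <- assess_chimerism(x, y, B = 300, seed = 99)
  b <- assess_chimerism(x, y, B = 300, seed = 99)
  expect_identical(a$delta_boot, b$delta_boot)
  expect_identical(glance(a), glance(b))
  expect_error(assess_chimerism(x, y, B = 50, seed = 1),
               class = "magqc_usage_error")
})

test_that("tidy/glance/autoplot expose the report", {
  repx <- assess_chimerism(c(10, 20), c(15, 15), B = 100, seed = 1)
  td <- tidy(repx)
  expect_equal(td$level, c("reads", "contigs"))
  gl <- glance(repx)
  expect_true(all(c("delta_richness", "ci_low", "ci_high",
                    "chimerism_flag") %in% names(gl)))
  expect_s3_class(autoplot(repx), "ggplot")
})
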