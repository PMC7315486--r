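random_calls <- function(n, seed, chroms = c("chr1", "chr2"), span = 5000) {
  withr::with_seed(seed, {
    as_meth_calls(data.frame(
      chrom = sample(chroms, n, replace = TRUE),
      pos = sample.int(span, n) - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      context = sample(c("CpG", "CHG", "CHH"), n, replace = TRUE,
                       prob = c(0.6, 0.2, 0.2)),
      count_meth = rbinom(n, 30, 0.4),
      count_unmeth = rbinom(n, 30, 0.6)
    ))
  })
}

test_that("both extractor dialects are detected and normalized to 0-based", {
  f <- withr::local_tempfile(fileext = ".cov")
  # coverage dialect: 1-based start/end, pct, meth, unmeth
  writeLines(c("chr1\t101\t101\t30\t3\t7", "chr1\t201\t201\t100\t5\t0"), f)
  cov <- read_methylation_calls(f)
  expect_equal(cov$pos, c(100L, 200L))
  expect_equal(cov$context, c("CpG", "CpG"))
  expect_equal(cov$count_meth / (cov$count_meth + cov$count_unmeth), c(0.3, 1))
  # cytosine-report dialect: strand column third, context sixth
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t101\t+\t3\t7\tCG\tCGT", "chr1\t102\t-\t0\t4\tCHH\tCAT"), g)
  rep <- read_methylation_calls(g)
  expect_equal(rep$pos, c(100L, 101L))
  expect_equal(rep$context, c("CpG", "CHH"))
  expect_equal(rep$strand, c("+", "-"))
  # empty file and error paths
  writeLines(character(0), f)
  expect_equal(nrow(read_methylation_calls(f)), 0)
  writeLines("chr1\tx\t101\t30\t3\t7", f)
  expect_error(read_methylation_calls(f), "line 1")
  writeLines("chr1\t101\t101\t90\t3\t7", f) # counts say 30%
  expect_warning(read_methylation_calls(f), "discrepancy")
})

test_that("coverage write/read round-trip is idempotent", {
  calls <- random_calls(200, seed = 1)
  cpg <- calls[calls$context == "CpG", ]
  cpg$strand <- "*"
  f <- withr::local_tempfile(fileext = ".cov")
  write_methylation_coverage(cpg, f)
  back <- read_methylation_calls(f)
  expect_equal(back$pos, cpg$pos)
  expect_equal(back$count_meth, cpg$count_meth)
  expect_equal(back$count_unmeth, cpg$count_unmeth)
})

test_that("locus pooling is the coverage-weighted fraction over CpG records", {
  calls <- as_meth_calls(data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40),
    context = c("CpG", "CpG", "CHH", "CpG"),
    count_meth = c(3, 7, 50, 10), count_unmeth = c(7, 3, 0, 0)
  ))
  loci <- data.frame(locus_id = c("L1", "L2", "L3"), chrom = "chr1",
                     start = c(0, 35, 100), end = c(35, 45, 110))
  lm <- locus_methylation(calls, loci)
  # L1 pools the two CpGs: (3+7)/20; CHH record at 30 is ignored
  expect_equal(lm$meth_fraction, c(0.5, 1, NA))
  expect_equal(lm$coverage, c(20L, 10L, 0L))
  # single fully methylated CpG
  one <- locus_methylation(
    as_meth_calls(data.frame(chrom = "chr1", pos = 5, count_meth = 10, count_unmeth = 0)),
    data.frame(locus_id = "x", chrom = "chr1", start = 5, end = 6))
  expect_equal(one$meth_fraction, 1)
  expect_error(locus_methylation(calls, data.frame(locus_id = c("a", "a"),
                                                   chrom = "chr1", start = 0, end = 1)),
               "unique")
})

test_that("locus pooling equals the all-pairs oracle on random instances", {
  for (seed in 1:8) {
    calls <- random_calls(300, seed = seed)
    loci <- withr::with_seed(seed + 500, {
      start <- sample.int(4800, 30) - 1L
      data.frame(locus_id = paste0("L", 1:30),
                 chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                 start = start, end = start + sample(c(1L, 50L, 200L), 30, replace = TRUE))
    })
    got <- locus_methylation(calls, loci)
    want <- oracle_locus_methylation(calls, loci)
    expect_equal(got$meth_fraction, want$meth_fraction)
    expect_equal(got$coverage, want$coverage)
    expect_true(all(got$meth_fraction >= 0 & got$meth_fraction <= 1, na.rm = TRUE))
  }
})

test_that("windowed context counts conserve the global counts exactly", {
  calls <- random_calls(500, seed = 21)
  s <- methylation_summary(calls, window = 1000)
  total <- dplyr::summarise(dplyr::group_by(s$windows, context),
                            count_meth = sum(count_meth),
                            count_unmeth = sum(count_unmeth), .groups = "drop")
  expect_equal(dplyr::arrange(total, context),
               dplyr::arrange(s$global[, names(total)], context))
  expect_true(all(s$windows$window_start %% 1000 == 0))
  # all-unmethylated CHH yields fraction 0
  chh <- as_meth_calls(data.frame(chrom = "c", pos = 1:5, context = "CHH",
                                  count_meth = 0, count_unmeth = 5))
  expect_equal(methylation_summary(chh)$global$fraction, 0)
})

test_that("spike-in conversion QC recovers simulated control error rates", {
  lam <- as_meth_calls(data.frame(chrom = "lambda", pos = 0:499,
                                  context = rep(c("CpG", "CHH"), 250),
                                  count_meth = c(2, rep(0, 499)),
                                  count_unmeth = 2))
  puc <- as_meth_calls(data.frame(chrom = "pUC19", pos = 0:99,
                                  count_meth = 95, count_unmeth = 5))
  qc <- conversion_qc(lam, puc)
  expect_equal(qc$conversion_efficiency, 1 - 2 / 1002)
  expect_equal(qc$methylation_retention, 0.95)
  expect_error(conversion_qc(lam[0, ], puc), "non-empty")

  # binomial simulation: recover known error rates within 3 SE
  n <- 2000; depth <- 20; err <- 0.005; ret <- 0.96
  sim_lam <- withr::with_seed(31, as_meth_calls(data.frame(
    chrom = "lambda", pos = seq_len(n), context = "CHH",
    count_meth = rbinom(n, depth, err), count_unmeth = depth)))
  sim_lam$count_unmeth <- depth - sim_lam$count_meth
  sim_puc <- withr::with_seed(32, as_meth_calls(data.frame(
    chrom = "pUC19", pos = seq_len(n),
    count_meth = rbinom(n, depth, ret), count_unmeth = 0)))
  sim_puc$count_unmeth <- depth - sim_puc$count_meth
  qc2 <- conversion_qc(sim_lam, sim_puc)
  se_eff <- sqrt(err * (1 - err) / (n * depth))
  se_ret <- sqrt(ret * (1 - ret) / (n * depth))
  expect_lt(abs(qc2$conversion_efficiency - (1 - err)), 3 * se_eff)
  expect_lt(abs(qc2$methylation_retention - ret), 3 * se_ret)
})

test_that("CpG coverage summary tallies covered CpGs and depths", {
  empty <- cpg_coverage_summary(random_calls(10, seed = 5)[0, ])
  expect_equal(empty$n_cpgs_covered, 0)
  expect_equal(empty$mean_depth, 0)
  three <- as_meth_calls(data.frame(chrom = "c", pos = 1:3,
                                    count_meth = c(1, 1, 1),
                                    count_unmeth = c(0, 1, 2)))
  cs <- cpg_coverage_summary(three)
  expect_equal(cs$n_cpgs_covered, 3)
  expect_equal(cs$mean_depth, 2)
  calls <- random_calls(400, seed = 6)
  cs2 <- cpg_coverage_summary(calls)
  cpg <- calls[calls$context == "CpG", ]
  depth <- cpg$count_meth + cpg$count_unmeth
  expect_equal(cs2$n_cpgs_covered, sum(depth >= 1))
  expect_equal(cs2$mean_depth, mean(depth[depth >= 1]))
  expect_equal(sum(attr(cs2, "histogram")$n), cs2$n_cpgs_covered)
})
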