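test_that("flanked regions grow symmetrically and clip at chromosome ends", {
  lay <- genome_layout("chr1", 20000)
  r <- tibble::tibble(cnvr_id = c("a", "b"), chrom = "chr1",
                      start = c(0, 6000), end = c(10000, 8000))
  f <- flank_regions(r, lay)
  expect_equal(f$start, c(0, 1000))
  expect_equal(f$end, c(15000, 13000))
  f0 <- flank_regions(r, lay, flank = 0)
  expect_equal(f0$start, r$start)
})

test_that("the SNP membership table conserves counts and handles edge sets", {
  scores <- tibble::tibble(chrom = "chr1", pos = c(10, 20, 30, 40),
                           score = c(5, 1, 4, 0))
  none <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric())
  t0 <- snp_region_table(scores, none)
  expect_equal(unname(t0["in_region", ]), c(0, 0))
  expect_equal(sum(t0), 4)
  flat <- dplyr::mutate(scores, score = 0)
  t1 <- snp_region_table(flat, tibble::tibble(chrom = "chr1", start = 0,
                                              end = 25))
  expect_equal(unname(t1[, "significant"]), c(0, 0))
})

test_that("SNP membership equals a per-SNP brute-force oracle", {
  set.seed(120)
  lay <- genome_layout("chr1", 1e4)
  regions <- random_intervals(15, lay, 500)
  scores <- tibble::tibble(chrom = "chr1", pos = sample.int(1e4, 300),
                           score = rexp(300))
  tab <- snp_region_table(scores, regions, threshold = 1)
  inside <- sapply(seq_len(nrow(scores)), function(i) {
    any(regions$start < scores$pos[i] & scores$pos[i] <= regions$end)
  })
  expect_equal(unname(tab["in_region", "significant"]),
               sum(inside & scores$score > 1))
  expect_equal(unname(tab["out_region", "not_significant"]),
               sum(!inside & scores$score <= 1))
  expect_equal(sum(tab), 300)
})

test_that("chi-square agrees with direct sum((O-E)^2/E) on every fixture", {
  fixtures <- list(matrix(c(10, 10, 10, 10), 2),
                   matrix(c(30, 5, 12, 40), 2),
                   matrix(c(3, 9, 27, 81, 10, 2), 2))
  for (tab in fixtures) {
    r <- chi_square(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - e)^2 / e))
    expect_equal(r$df, (nrow(tab) - 1) * (ncol(tab) - 1))
  }
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("CNV-state cross-tabulation counts every (CNVR, sample) pair once", {
  regions <- tibble::tibble(
    cnvr_id = c("r1", "r2"), chrom = "chr1", start = c(0, 100),
    end = c(10, 110), length = 10, class = c("mixed", "deletion_only"),
    carrier_count = c(3, 2), n_calls = c(3, 2), frequency = c(.3, .2))
  copies <- tibble::tibble(
    cnvr_id = c("r1", "r1", "r1", "r2", "r2"),
    sample = c("s1", "s2", "s3", "s1", "s4"),
    copy_number = c(1, 3, 3, 1, 1), fractional_copy = c(1, 3, 3, 1, 1))
  cs <- cnvr_set(regions, copies, 10)
  out <- cnv_state_by_selection(cs, c(TRUE, FALSE))
  expect_equal(unname(out$table["selected", ]), c(1, 7, 2))
  expect_equal(unname(out$table["unselected", ]), c(2, 8, 0))
  expect_equal(sum(out$table), 2 * 10)
  expect_equal(out$row_summary$mean_cnv_frequency_pct,
               c(100 * 3 / 10, 100 * 2 / 10))
})

test_that("an all-reference row reports 0% CNV frequency", {
  regions <- tibble::tibble(
    cnvr_id = c("r1", "r2"), chrom = "chr1", start = c(0, 100),
    end = c(10, 110), length = 10, class = "deletion_only",
    carrier_count = c(2, 2), n_calls = c(2, 2), frequency = .2)
  copies <- tibble::tibble(cnvr_id = c("r2", "r2"), sample = c("s1", "s2"),
                           copy_number = c(1, 1), fractional_copy = c(1, 1))
  cs <- cnvr_set(regions, copies, 10)
  out <- cnv_state_by_selection(cs, c(TRUE, FALSE))
  expect_equal(out$row_summary$mean_cnv_frequency_pct[1], 0)
})

test_that("independence expectation for joint tagged/selected counts", {
  j <- joint_expected(2693, 372, 7608)
  expect_equal(j$expected, 2693 * 372 / 7608)
  expect_equal(j$expected_rounded, 132)
  expect_equal(joint_expected(0, 50, 100)$expected, 0)
  expect_equal(joint_expected(100, 50, 100)$expected, 50)
  expect_error(joint_expected(10, 5, 0), "positive")
})

test_that("joint excess test behaves at independence and detects strong excess", {
  # observed exactly at the margins product -> p ~ 1
  at_null <- joint_excess_test(50, 100, 500, 1000)
  expect_equal(at_null$observed, at_null$expected)
  expect_gt(at_null$p_value, 0.9)
  strong <- joint_excess_test(222, 2693, 372, 7608)
  expect_lt(strong$p_value, 1e-3)
  fis <- joint_excess_test(222, 2693, 372, 7608, method = "fisher")
  expect_lt(fis$p_value, 1e-3)
  expect_error(joint_excess_test(400, 2693, 372, 7608), "margin")
})

test_that("joint excess test holds its size under simulated independence", {
  set.seed(130)
  n_rej <- 0; n_sims <- 200
  for (i in seq_len(n_sims)) {
    tagged <- runif(400) < 0.3
    selected <- runif(400) < 0.2
    p <- joint_excess_test(sum(tagged & selected), sum(tagged),
                           sum(selected), 400)$p_value
    if (p < 0.05) n_rej <- n_rej + 1
  }
  # binomial band around alpha = 0.05
  expect_lt(abs(n_rej / n_sims - 0.05), 3 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("selected-CNVR flags respond to score placement", {
  lay <- genome_layout("chr1", 1e5)
  r <- tibble::tibble(cnvr_id = c("a", "b"), chrom = "chr1",
                      start = c(10000, 50000), end = c(12000, 52000))
  scores <- tibble::tibble(chrom = "chr1", pos = c(11000, 49000, 80000),
                           score = c(5, 4, 6))
  f <- flag_selected(r, scores, lay)
  # 49000 is inside b's 5 kb flank; 80000 is outside everything
  expect_equal(f$selected, c(TRUE, TRUE))
  f0 <- flag_selected(r, scores, lay, flank = 0)
  expect_equal(f0$selected, c(TRUE, FALSE))
})

test_that("the membership chi-square grows with the configured score enrichment", {
  stat_at <- function(ratio, seed) {
    cfg <- cohort_config(seed = seed, layout = genome_layout("chr1", 1e6),
                         n_true_cnvrs = 25, fraction_selected = 0.5,
                         selection_enrichment = ratio,
                         background_sig_rate = 0.02, snp_spacing = 200,
                         fp_rate = 0, n_outlier_samples = 0)
    co <- generate_cohort(cfg)
    flanked <- flank_regions(dplyr::filter(co$truth, selected), co$layout)
    # threshold at the quantile matching the configured background rate
    thr <- -log10(0.02)
    chi_square(snp_region_table(co$scores, flanked, threshold = thr))$statistic
  }
  lo <- sapply(1:4, function(s) stat_at(1, s))
  hi <- sapply(1:4, function(s) stat_at(5, s + 100))
  pv <- stats::wilcox.test(hi, lo, alternative = "greater")$p.value
  expect_lt(pv, 0.05)
})
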