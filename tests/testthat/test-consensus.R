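calls_tbl <- function(...) {
  tibble::tribble(~chrom, ~start, ~end, ~sample, ~copy_number, ...) |>
    dplyr::mutate(fractional_copy = as.numeric(copy_number),
                  caller = "test")
}

test_that("overlapping calls merge into one CNVR with union boundaries", {
  calls <- calls_tbl("chr1", 100, 200, "S1", 1,
                     "chr1", 150, 300, "S2", 3)
  set <- merge_calls_to_cnvr(calls)
  expect_equal(nrow(set$regions), 1)
  expect_equal(set$regions$start, 100)
  expect_equal(set$regions$end, 300)
  expect_equal(set$regions$class, "mixed")
  expect_equal(set$regions$carrier_count, 2)
})

test_that("disjoint calls give distinct CNVRs and call order does not matter", {
  calls <- calls_tbl("chr1", 100, 200, "S1", 1,
                     "chr1", 500, 600, "S2", 1,
                     "chr2", 100, 200, "S1", 3)
  set <- merge_calls_to_cnvr(calls)
  expect_equal(nrow(set$regions), 3)
  set2 <- merge_calls_to_cnvr(calls[c(3, 1, 2), ])
  expect_equal(as.data.frame(set$regions), as.data.frame(set2$regions))
  expect_equal(dplyr::arrange(set$copies, cnvr_id, sample),
               dplyr::arrange(set2$copies, cnvr_id, sample))
})

test_that("merged regions equal the per-base connected-components oracle", {
  set.seed(33)
  lay <- toy_layout(5000)
  ints <- random_intervals(500, lay, max_len = 30)
  calls <- ints |>
    dplyr::mutate(sample = sprintf("S%02d", sample.int(20, 500, TRUE)),
                  copy_number = sample(c(1, 3), 500, TRUE),
                  fractional_copy = copy_number, caller = "x")
  set <- merge_calls_to_cnvr(calls)
  oracle <- brute_merge(calls, lay) |> dplyr::arrange(chrom, start)
  expect_equal(as.data.frame(set$regions[, c("chrom", "start", "end")]),
               as.data.frame(oracle))
})

test_that("a sample's copy state comes from its longest call in the region", {
  calls <- calls_tbl("chr1", 100, 400, "S1", 3,
                     "chr1", 350, 420, "S1", 1)
  set <- merge_calls_to_cnvr(calls)
  expect_equal(set$copies$copy_number, 3)
})

test_that("region classification follows the copy-state sign rules", {
  expect_equal(classify_region(c(1, 1, 2, 2)), "deletion_only")
  expect_equal(classify_region(c(3, 4)), "insertion_only")
  expect_equal(classify_region(c(1, 3)), "mixed")
  expect_error(classify_region(c(2, 2)), "all-reference")
})

test_that("singleton CNVRs are removed, multi-carrier regions kept", {
  calls <- calls_tbl("chr1", 100, 200, "S1", 1,
                     "chr1", 500, 600, "S1", 1,
                     "chr1", 550, 650, "S2", 1,
                     "chr1", 900, 950, "S3", 3,
                     "chr1", 910, 940, "S4", 3,
                     "chr1", 905, 930, "S5", 3)
  set <- merge_calls_to_cnvr(calls)
  kept <- filter_singletons(set)
  # hand count: region at 100-200 has 1 carrier, the others 2 and 3
  expect_equal(nrow(set$regions), 3)
  expect_equal(nrow(kept$regions), 2)
  expect_true(all(kept$regions$carrier_count >= 2))
})

test_that("consensus intersection keeps A-regions with >= 1 bp of B overlap", {
  a <- merge_calls_to_cnvr(calls_tbl("chr1", 0, 10, "S1", 1,
                                     "chr1", 0, 10, "S2", 1))
  b_ov <- tibble::tibble(chrom = "chr1", start = 9, end = 20)
  b_touch <- tibble::tibble(chrom = "chr1", start = 10, end = 20)
  expect_equal(nrow(consensus_intersect(a, b_ov)$regions), 1)
  expect_equal(nrow(consensus_intersect(a, b_touch)$regions), 0)
})

test_that("consensus intersection matches a brute-force pairwise check", {
  set.seed(44)
  lay <- toy_layout(5000)
  mk <- function(n) {
    ints <- random_intervals(n, lay, max_len = 40)
    calls <- dplyr::mutate(ints, sample = sprintf("S%d", seq_len(n) %% 7),
                           copy_number = 1, fractional_copy = 1,
                           caller = "x")
    merge_calls_to_cnvr(calls)
  }
  a <- mk(80); b <- mk(80)
  got <- consensus_intersect(a, b)$regions
  oracle <- a$regions[brute_overlaps_any(a$regions, b$regions, lay), ]
  expect_equal(got$cnvr_id, oracle$cnvr_id)
})

test_that("outlier detection flags extreme call counts and refuses tiny cohorts", {
  equal <- tibble::tibble(chrom = "chr1",
                          start = seq(0, 11 * 100, by = 100)[1:12],
                          end = seq(0, 11 * 100, by = 100)[1:12] + 50,
                          sample = sprintf("S%02d", 1:12),
                          copy_number = 1, fractional_copy = 1, caller = "x")
  rep <- detect_outlier_samples(equal)
  expect_length(rep$outliers, 0)

  # one sample at 10x the median of 59 others: median 2, MAD 0 -> flagged
  set.seed(55)
  base <- tidyr::expand_grid(sample = sprintf("S%02d", 1:59), i = 1:2)
  hot <- tidyr::expand_grid(sample = "HOT", i = 1:20)
  calls <- dplyr::bind_rows(base, hot) |>
    dplyr::mutate(chrom = "chr1", start = sample.int(9000, dplyr::n()),
                  end = start + 10, copy_number = 1, fractional_copy = 1,
                  caller = "x")
  rep2 <- detect_outlier_samples(calls)
  expect_equal(rep2$outliers, "HOT")
  expect_true(rep2$test$mean_outliers > rep2$test$mean_retained)

  expect_error(detect_outlier_samples(equal[1:5, ]), "at least 10")
})

test_that("region summary arithmetic matches hand computation", {
  calls <- calls_tbl("chr1", 0, 1000, "S1", 1,
                     "chr1", 0, 1000, "S2", 1,
                     "chr1", 5000, 8000, "S1", 3,
                     "chr1", 5000, 8000, "S2", 3,
                     "chr1", 5000, 8000, "S3", 3,
                     "chr1", 5000, 8000, "S4", 3)
  set <- merge_calls_to_cnvr(calls, n_samples = 4)
  s <- region_summary(set)
  expect_equal(s$n_cnvr, 2)
  expect_equal(s$mean_length_kb, 2)      # (1 kb + 3 kb) / 2
  expect_equal(s$mean_cnv_per_cnvr, 3)   # (2 + 4) / 2
  expect_equal(s$mean_cnvr_per_individual, 6 / 4) # total CNV / n_samples
})

test_that("the consensus chain recovers true CNVRs on noise-free synthetic data", {
  cfg <- cohort_config(seed = 60,
                       layout = genome_layout(c("chr1", "chr2"), c(3e6, 3e6)),
                       n_true_cnvrs = 80, caller_a_jitter_sd = 0,
                       caller_a_frac_sd = 0, fp_rate = 0,
                       n_outlier_samples = 0, snp_spacing = 5000)
  co <- generate_cohort(cfg)
  res <- build_consensus(co$calls_a, co$calls_b, co$samples)
  got <- res$consensus$regions
  # every consensus region should coincide with a true CNVR (Jaccard >= .95)
  pr <- overlap_pairs(got, co$truth)
  jac <- purrr::map_dbl(seq_len(nrow(pr)), function(k) {
    g <- got[pr$a_row[k], ]; t <- co$truth[pr$b_row[k], ]
    inter <- min(g$end, t$end) - max(g$start, t$start)
    inter / (max(g$end, t$end) - min(g$start, t$start))
  })
  best <- tapply(jac, pr$a_row, max)
  expect_true(mean(best >= 0.95) >= 0.95)
})

test_that("configured outlier samples are recovered from the synthetic cohort", {
  cfg <- cohort_config(seed = 61)
  co <- generate_cohort(cfg)
  res <- build_consensus(co$calls_a, co$calls_b, co$samples)
  expect_setequal(res$outliers$outliers, co$outlier_samples)
  expect_equal(res$log, c("merge_per_caller", "outlier_removal", "re_merge",
                          "singleton_filter", "consensus_intersect"))
})
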