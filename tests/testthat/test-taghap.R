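# independent single-linkage + string-count oracle for haplotype assembly
oracle_clusters <- function(haps, pos, thr, win) {
  p <- nrow(haps)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r2 <- ld_r2(haps[i, ], haps[j, ])
      if (!is.na(r2) && r2 > thr && abs(pos[i] - pos[j]) <= win) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(p), find, integer(1))
}

test_that("LD r-squared matches the textbook D-squared formula", {
  # chromosome haplotype counts AB=40 Ab=10 aB=10 ab=40 of 100:
  # D = 0.40 - 0.5*0.5 = 0.15, r2 = 0.15^2 / (0.5^4) = 0.36
  a <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(ld_r2(a, b), 0.36)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 1 - a), 1) # complement: correlation squared
  expect_true(is.na(ld_r2(a, rep(1, 100)))) # monomorphic undefined
})

test_that("candidate windows clip at chromosome ends and respect flank = 0", {
  lay <- genome_layout("chr1", 20000)
  expect_equal(candidate_window("chr1", 0, 10000, lay)$end, 15000)
  expect_equal(candidate_window("chr1", 0, 10000, lay)$start, 0)
  w <- candidate_window("chr1", 6000, 8000, lay)
  expect_equal(c(w$start, w$end), c(1000, 13000))
  w0 <- candidate_window("chr1", 6000, 8000, lay, flank = 0)
  expect_equal(c(w0$start, w0$end), c(6000, 8000))
})

test_that("two SNPs in perfect LD define complementary haplotype dosages", {
  # 8 chromosomes: strings 11 and 00 only
  h <- rbind(c(1, 1, 0, 0, 1, 1, 0, 0),
             c(1, 1, 0, 0, 1, 1, 0, 0))
  s <- make_phased(h)
  hb <- build_haplotypes(s)
  expect_equal(nrow(hb$haplotypes), 2)
  expect_setequal(hb$haplotypes$alleles, c("11", "00"))
  expect_equal(unname(colSums(hb$dosage)), rep(2, 4))
  d11 <- hb$dosage[hb$haplotypes$alleles == "11", ]
  d00 <- hb$dosage[hb$haplotypes$alleles == "00", ]
  expect_equal(unname(d11 + d00), rep(2, 4))
})

test_that("no haplotypes are assembled when all pairwise LD is weak", {
  set.seed(90)
  h <- matrix(rbinom(5 * 60, 1, 0.5), nrow = 5) # independent SNPs
  hb <- build_haplotypes(make_phased(h))
  expect_equal(nrow(hb$haplotypes), 0)
})

test_that("assembly equals a brute-force single-linkage and string-count oracle", {
  set.seed(91)
  for (rep in 1:4) {
    # founder structure so some pairs exceed the threshold
    founders <- matrix(rbinom(5 * 3, 1, 0.5), nrow = 5)
    pick <- sample.int(3, 30, replace = TRUE)
    h <- founders[, pick]
    s <- make_phased(h)
    hb <- build_haplotypes(s, r2_threshold = 0.6)
    poly <- apply(h, 1, function(z) var(z) > 0)
    hp <- h[poly, , drop = FALSE]
    pos_poly <- 100 * which(poly) - 1 # pos0 of the polymorphic SNPs
    cl <- oracle_clusters(hp, pos_poly, 0.6, 50000)
    multi <- names(table(cl))[table(cl) >= 2]
    n_expected <- 0
    for (m in multi) {
      strings <- apply(hp[cl == as.integer(m), , drop = FALSE], 2, paste,
                       collapse = "")
      n_expected <- n_expected + sum(table(strings) >= 2)
    }
    expect_equal(nrow(hb$haplotypes), n_expected)
    if (nrow(hb$haplotypes) > 0) {
      # dosages re-counted directly from strings
      for (k in seq_len(nrow(hb$haplotypes))) {
        idx <- which(pos_poly %in% hb$haplotypes$positions[[k]])
        expect_length(unique(cl[idx]), 1) # one oracle cluster
        strings <- apply(hp[idx, , drop = FALSE], 2, paste, collapse = "")
        per_sample <- colSums(matrix(strings == hb$haplotypes$alleles[k],
                                     nrow = 2))
        expect_equal(unname(hb$dosage[k, ]), per_sample)
      }
    }
  }
})

test_that("uninformative haplotypes (carriers share one copy number) are dropped", {
  expect_false(informative_filter(c(1, 1, 0, 0), c(2, 2, 2, 2)))
  expect_true(informative_filter(c(1, 1, 0, 0), c(1, 2, 2, 2)))
  expect_false(informative_filter(c(1, 1, 1, 1), c(1, 2, 3, 2))) # constant dosage
  expect_error(informative_filter(c(0, 0, 0, 0), c(1, 2, 2, 2)), "zero carriers")
})

test_that("a perfect dosage-copy relationship gives slope 1, r2 1, p ~ 0", {
  fit <- copy_regression(c(0, 1, 2, 0, 1, 2), c(2, 3, 4, 2, 3, 4))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$p_slope, 1e-12)
})

test_that("regression matches hand-solved normal equations on a 6-point fixture", {
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(2.0, 2.2, 2.9, 3.1, 4.2, 3.8)
  fit <- copy_regression(x, y)
  # by hand: sxx = 4, sxy = 3.8 -> slope 0.95; SSE = 0.1233333,
  # SST = 3.7333333 -> r2 = 0.9669643; se = sqrt(SSE/4/4) = 0.0877971
  expect_equal(fit$slope, 0.95)
  expect_equal(fit$intercept, 2.0833333, tolerance = 1e-6)
  expect_equal(fit$r_squared, 0.9669643, tolerance = 1e-6)
  se <- sqrt((0.1233333 / 4) / 4)
  expect_equal(fit$p_slope, 2 * pt(0.95 / se, df = 4, lower.tail = FALSE),
               tolerance = 1e-5)
  # invariant under sample reordering
  o <- c(4, 2, 6, 1, 3, 5)
  expect_equal(copy_regression(x[o], y[o]), fit)
})

test_that("regression p-values are roughly uniform under the null", {
  set.seed(92)
  p <- replicate(200, {
    copy_regression(sample(0:2, 60, replace = TRUE), rnorm(60, 2))$p_slope
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("noise-free taggable CNVRs are tagged with the designated haplotype on top", {
  cfg <- cohort_config(seed = 95, layout = genome_layout("chr1", 1.5e6),
                       n_true_cnvrs = 25, fraction_taggable = 1,
                       caller_a_jitter_sd = 0, caller_a_frac_sd = 0,
                       fp_rate = 0, n_outlier_samples = 0, missing_rate = 0)
  co <- generate_cohort(cfg)
  cons <- merge_calls_to_cnvr(co$calls_a, n_samples = nrow(co$samples))
  tags <- tag_cnvrs(cons, co$snps, co$layout)
  expect_gt(mean(tags$cnvrs$tagged), 0.8)
  # for tagged CNVRs, the best haplotype explains copy number essentially
  # perfectly (it is the designated founder background)
  best <- tags$associations |>
    dplyr::filter(significant) |>
    dplyr::group_by(cnvr_id) |>
    dplyr::slice_min(p_adjusted, n = 1, with_ties = FALSE)
  expect_gt(median(best$r_squared), 0.95)
})

test_that("per-population runs report tagging for every population", {
  cfg <- cohort_config(seed = 96, layout = genome_layout("chr1", 8e5),
                       n_true_cnvrs = 10, fraction_taggable = 1,
                       caller_a_jitter_sd = 0, caller_a_frac_sd = 0,
                       fp_rate = 0, n_outlier_samples = 0, missing_rate = 0)
  co <- generate_cohort(cfg)
  cons <- merge_calls_to_cnvr(co$calls_a, n_samples = nrow(co$samples))
  tags <- tag_cnvrs(cons, co$snps, co$layout, samples = co$samples)
  expect_setequal(unique(tags$per_population$population),
                  co$samples$population)
  expect_equal(nrow(tags$per_population),
               3 * nrow(cons$regions))
})
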