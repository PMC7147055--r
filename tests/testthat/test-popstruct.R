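test_that("allele-pair encoding splits copies evenly and caps at (4,4)", {
  e <- encode_alleles(c(0, 1, 2, 3, 4, 5, 6, 7))
  expect_equal(e$a1, c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(e$a2, c(1, 2, 2, 3, 3, 4, 4, 4))
  expect_error(encode_alleles(-1), "non-negative")
})

test_that("encode/decode round trip returns min(copy, 6) for all copies", {
  c_in <- 0:12
  e <- encode_alleles(c_in)
  expect_equal(decode_alleles(e$a1, e$a2), pmin(c_in, 6))
  expect_true(all(e$a1 <= e$a2))
})

test_that("copy matrix defaults absent calls to the diploid reference", {
  regions <- tibble::tibble(cnvr_id = c("r1", "r2"), chrom = "chr1",
                            start = c(0, 100), end = c(10, 110),
                            length = 10, class = "deletion_only",
                            carrier_count = 2, n_calls = 2, frequency = .5)
  copies <- tibble::tibble(cnvr_id = c("r1", "r2"), sample = c("s1", "s2"),
                           copy_number = c(0, 1), fractional_copy = c(0, 1))
  m <- copy_matrix(cnvr_set(regions, copies, 3),
                   samples = c("s1", "s2", "s3"))
  expect_equal(unname(m[, "r1"]), c(0, 2, 2))
  expect_equal(unname(m[, "r2"]), c(2, 1, 2))
})

test_that("PC1 separates two clusters of identical rows exactly", {
  m <- rbind(matrix(1, 5, 20), matrix(3, 5, 20))
  rownames(m) <- sprintf("s%02d", 1:10)
  m[1, 1] <- 1.001 # avoid a fully degenerate matrix
  p <- suppressWarnings(cnv_pca(m, k = 2))
  pc1 <- p$scores$PC1
  expect_true(all(sign(pc1[1:5]) == sign(pc1[1])))
  expect_true(all(sign(pc1[6:10]) == -sign(pc1[1])))
})

test_that("permuting samples permutes PCA coordinates identically", {
  set.seed(140)
  m <- matrix(sample(0:4, 200, replace = TRUE), nrow = 10)
  rownames(m) <- sprintf("s%02d", 1:10)
  p1 <- suppressWarnings(cnv_pca(m, k = 3))
  o <- sample(10)
  p2 <- suppressWarnings(cnv_pca(m[o, ], k = 3))
  a <- dplyr::arrange(p1$scores, sample)
  b <- dplyr::arrange(p2$scores, sample)
  for (pc in c("PC1", "PC2", "PC3")) {
    expect_equal(abs(a[[pc]]), abs(b[[pc]]), tolerance = 1e-8)
  }
})

test_that("k above the matrix rank is reduced with a warning", {
  m <- matrix(rep(c(0, 1), each = 10), nrow = 4, ncol = 5)
  rownames(m) <- letters[1:4]
  m[1, 1] <- 2
  expect_warning(p <- cnv_pca(m, k = 10), "rank")
  expect_lte(p$k, 4)
})

wc_fixture <- function() {
  # two pops of 10; deletion-allele frequencies 0.2 and 0.8, all carriers het
  samples <- tibble::tibble(sample = sprintf("S%02d", 1:20),
                            population = rep(c("A", "B"), each = 10),
                            group = "G")
  copies <- dplyr::bind_rows(
    tibble::tibble(cnvr_id = "x", sample = sprintf("S%02d", 1:4),
                   copy_number = 1, fractional_copy = 1),
    tibble::tibble(cnvr_id = "x", sample = sprintf("S%02d", 11:16),
                   copy_number = 0, fractional_copy = 0),
    tibble::tibble(cnvr_id = "x", sample = sprintf("S%02d", 17:20),
                   copy_number = 1, fractional_copy = 1))
  regions <- tibble::tibble(cnvr_id = "x", chrom = "c", start = 0, end = 100,
                            length = 100, class = "deletion_only",
                            carrier_count = 14, n_calls = 14, frequency = .7)
  list(set = cnvr_set(regions, copies, 20), samples = samples)
}

test_that("Weir-Cockerham components match the hand-evaluated two-population oracle", {
  fx <- wc_fixture()
  f <- fst_deletions(fx$set, fx$samples)
  # by hand: r=2, nbar=10, nc=10, pbar=0.5, s2=0.18, hbar=0.4
  #   a = 0.18 - (0.25 - 0.09 - 0.1)/9 = 0.17333...
  #   b = (10/9)(0.25 - 0.09 - 0.19)   = -0.03333...
  #   c = 0.2;  F_ST = a/(a+b+c) = 0.509803921568...
  expect_equal(f$per_locus$a, 0.17333333333333, tolerance = 1e-10)
  expect_equal(f$per_locus$b, -0.03333333333333, tolerance = 1e-10)
  expect_equal(f$per_locus$c, 0.2, tolerance = 1e-12)
  expect_equal(f$per_locus$fst, 0.50980392156863, tolerance = 1e-10)
  expect_equal(f$global, f$per_locus$fst)
  expect_equal(f$pairwise["A", "B"], f$global)
})

test_that("equal allele frequencies give near-zero F_ST, fixed differences near one", {
  samples <- tibble::tibble(sample = sprintf("S%02d", 1:20),
                            population = rep(c("A", "B"), each = 10),
                            group = "G")
  mk <- function(copy_by_sample) {
    idx <- which(copy_by_sample != 2)
    copies <- tibble::tibble(cnvr_id = "x",
                             sample = sprintf("S%02d", idx),
                             copy_number = copy_by_sample[idx],
                             fractional_copy = copy_by_sample[idx])
    regions <- tibble::tibble(cnvr_id = "x", chrom = "c", start = 0,
                              end = 100, length = 100,
                              class = "deletion_only",
                              carrier_count = length(idx),
                              n_calls = length(idx),
                              frequency = length(idx) / 20)
    cnvr_set(regions, copies, 20)
  }
  same <- mk(rep(c(1, 2), 10)) # freq .25 in both pops
  f_same <- fst_deletions(same, samples)
  expect_lt(abs(f_same$global), 0.06)
  fixed <- mk(rep(c(0, 2), each = 10)) # del fixed in A, absent in B
  f_fixed <- fst_deletions(fixed, samples)
  expect_equal(f_fixed$global, 1)
})

test_that("monomorphic loci are excluded and the pairwise matrix is symmetric", {
  fx <- wc_fixture()
  # add a monomorphic deletion locus (deletion fixed in every sample)
  mono_copies <- tibble::tibble(cnvr_id = "m",
                                sample = sprintf("S%02d", 1:20),
                                copy_number = 0, fractional_copy = 0)
  regions <- dplyr::bind_rows(
    fx$set$regions,
    tibble::tibble(cnvr_id = "m", chrom = "c", start = 200, end = 300,
                   length = 100, class = "deletion_only",
                   carrier_count = 20, n_calls = 20, frequency = 1))
  cs <- cnvr_set(regions, dplyr::bind_rows(fx$set$copies, mono_copies), 20)
  f <- fst_deletions(cs, fx$samples)
  expect_true(is.na(f$per_locus$fst[f$per_locus$cnvr_id == "m"]))
  expect_equal(f$global, 0.50980392156863, tolerance = 1e-10)
  expect_equal(f$pairwise, t(f$pairwise))
  expect_equal(unname(diag(f$pairwise)), rep(0, 2))
})

test_that("high-F_ST flagging uses mean + k*SD of the defined distribution", {
  v <- c(rep(0.1, 19), 0.9)
  out <- high_fst_cnvrs(v)
  expect_equal(sum(out$high_fst), 1)
  expect_true(out$high_fst[20])
  none <- high_fst_cnvrs(rep(0.2, 12))
  expect_equal(sum(none$high_fst), 0)
  # k = 0 flags everything above the mean
  k0 <- high_fst_cnvrs(c(rep(0.1, 10), rep(0.3, 5)), k = 0)
  expect_equal(sum(k0$high_fst), 5)
  expect_error(high_fst_cnvrs(rep(0.1, 5)), "at least 10")
})

test_that("estimated F_ST increases with configured population divergence", {
  global_at <- function(div, seed) {
    cfg <- cohort_config(seed = seed, layout = genome_layout("chr1", 2e6),
                         n_true_cnvrs = 50, fraction_taggable = 0,
                         group_divergence = div, pop_divergence = div,
                         fp_rate = 0, n_outlier_samples = 0,
                         snp_spacing = 5000)
    co <- generate_cohort(cfg)
    cons <- merge_calls_to_cnvr(co$calls_a, n_samples = nrow(co$samples))
    fst_deletions(cons, co$samples)$global
  }
  lo <- sapply(1:4, function(s) global_at(0.01, s))
  hi <- sapply(1:4, function(s) global_at(0.25, s + 50))
  expect_lt(stats::wilcox.test(hi, lo, alternative = "greater")$p.value,
            0.05)
})
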