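# Synthetic-cohort generator. Emulates the data regime the pipeline is
# built for: two CNV callers of very different granularity (a fine caller
# with small boundary jitter, a coarse caller that merges nearby loci),
# population-stratified CNV frequencies (hierarchical Balding-Nichols:
# group-level then population-level divergence from a cohort-wide base
# frequency), CNVs arising on a single haplotype background (taggable by
# SNPs) versus recurrent backgrounds (untaggable), phased SNPs with
# LD-block structure from a small founder-haplotype pool per block, and
# selection scores enriched inside designated CNVRs. Everything is
# reproducible from one seed.

#' Configuration for a synthetic cohort
#'
#' All values have documented defaults; the seed is mandatory. Lengths are
#' bp, rates are probabilities.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param layout Genome layout (default 2 chromosomes x 10 Mb).
#' @param populations Tibble `population`, `group`, `n` (default 3
#'   populations of 20 samples in 2 linguistic groups).
#' @param n_true_cnvrs Number of true CNVRs (default 300).
#' @param cnvr_meanlog,cnvr_sdlog Log-normal CNVR length parameters
#'   (default median 5 kb, sdlog 0.6).
#' @param freq_beta Shape parameters of the beta base distribution of the
#'   per-chromosome CNV allele frequency (default mean 0.08, so carrier
#'   frequencies centre near 15%).
#' @param group_divergence,pop_divergence Balding-Nichols F at the group
#'   and population level (defaults 0.08 and 0.02).
#' @param fraction_taggable Fraction of CNVRs on a single haplotype
#'   background (default 0.6).
#' @param fraction_selected Fraction of CNVRs designated as under selection
#'   (default 0.05).
#' @param selection_enrichment Multiplier on the probability that a SNP
#'   inside a selected CNVR scores above 3 (default 3).
#' @param background_sig_rate P(score > 3) for background SNPs (default
#'   1e-3, i.e. scores are -log10 of a uniform p).
#' @param snp_spacing Mean SNP spacing in bp (default 500).
#' @param founder_pool Founder haplotypes per LD block (default 4; a small
#'   pool gives the strong within-block LD the tagging model assumes).
#' @param block_bp LD block length outside CNVR windows (default 20000).
#' @param caller_a_jitter_sd Caller-A boundary jitter SD in bp (default
#'   200).
#' @param caller_a_frac_sd SD of fractional-copy noise (default 0.15, so
#'   rounding recovers the true integer >99% of the time).
#' @param caller_b_merge_distance Caller B merges true CNVRs closer than
#'   this (default 20000).
#' @param caller_b_jitter_sd Caller-B boundary jitter SD (default 1000).
#' @param fp_rate False-positive call rate per sample per true CNVR
#'   (default 0.02).
#' @param n_outlier_samples Samples with inflated false-positive rates
#'   (default 3).
#' @param outlier_fp_multiplier FP multiplier for outlier samples (default
#'   10).
#' @param known_db_coverage Fraction of true CNVRs present in the
#'   known-region database (default 0.97).
#' @param missing_rate Per-genotype missing probability (default 0.002).
#' @param flank Flank used to reserve SNP windows around taggable CNVRs
#'   (default 5000, matching the tagging candidate window).
#' @return Object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(seed,
                          layout = genome_layout(c("chr1", "chr2"),
                                                 c(1e7, 1e7)),
                          populations = tibble(
                            population = c("P1", "P2", "P3"),
                            group = c("G1", "G1", "G2"),
                            n = c(20L, 20L, 20L)),
                          n_true_cnvrs = 300,
                          cnvr_meanlog = log(5000), cnvr_sdlog = 0.6,
                          freq_beta = c(0.8, 9.2),
                          group_divergence = 0.08, pop_divergence = 0.02,
                          fraction_taggable = 0.6,
                          fraction_selected = 0.05,
                          selection_enrichment = 3,
                          background_sig_rate = 1e-3,
                          snp_spacing = 500,
                          founder_pool = 4, block_bp = 20000,
                          caller_a_jitter_sd = 200, caller_a_frac_sd = 0.15,
                          caller_b_merge_distance = 20000,
                          caller_b_jitter_sd = 1000,
                          fp_rate = 0.02,
                          n_outlier_samples = 3, outlier_fp_multiplier = 10,
                          known_db_coverage = 0.97,
                          missing_rate = 0.002,
                          flank = 5000) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(fraction_taggable, fraction_selected, background_sig_rate,
             fp_rate, known_db_coverage, missing_rate,
             group_divergence, pop_divergence)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  # feasibility: the genome must hold the CNVRs plus their reserved gaps
  need <- n_true_cnvrs * (exp(cnvr_meanlog + cnvr_sdlog^2) + 2 * flank + 2000)
  if (need > 0.8 * sum(layout$length)) {
    abort(paste0("infeasible config: ", n_true_cnvrs,
                 " CNVRs of median length ", round(exp(cnvr_meanlog)),
                 " bp (plus reserved flanks) will not fit the genome"))
  }
  structure(cfg, class = "cohort_config")
}

# Balding-Nichols draw: a frequency around p with divergence F.
.bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  k <- (1 - f) / f
  pmin(pmax(rbeta(length(p), p * k, (1 - p) * k), 0.005), 0.95)
}

# Place n non-overlapping intervals (given lengths) with at least min_gap
# bp between them, uniformly by rejection.
.place_disjoint <- function(lengths, layout, min_gap) {
  placed <- tibble(chrom = character(), start = numeric(), end = numeric())
  for (L in lengths) {
    for (try in 1:500) {
      valid <- pmax(layout$length - L + 1, 0)
      ci <- sample.int(nrow(layout), 1, prob = valid)
      s <- sample.int(valid[ci], 1) - 1
      cand <- tibble(chrom = layout$chrom[ci],
                     start = max(0, s - min_gap),
                     end = min(layout$length[ci], s + L + min_gap))
      if (!any(overlaps_any(cand, placed))) {
        placed <- bind_rows(placed, tibble(chrom = layout$chrom[ci],
                                           start = s, end = s + L))
        break
      }
      if (try == 500) abort("could not place CNVRs without overlap; reduce n_true_cnvrs")
    }
  }
  placed
}

#' Generate a complete synthetic cohort
#'
#' Produces ground truth plus every input the pipeline reads: two caller
#' call sets, phased SNPs with LD blocks, selection scores, a known-region
#' database and the sample roster. See [cohort_config()] for the knobs.
#'
#' @param config A [cohort_config()].
#' @return Object of class `cnv_cohort`: `truth` (CNVR-level ground truth
#'   with taggable/selected flags and the designated tag haplotype),
#'   `truth_freq` (per-population allele frequencies), `truth_copies`
#'   (per-sample true copies at carried CNVRs), `calls_a`, `calls_b`,
#'   `snps`, `scores`, `known`, `samples`, `outlier_samples`, `layout`,
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  layout <- cfg$layout

  ## samples -----------------------------------------------------------
  pops <- cfg$populations
  samples <- pops |>
    group_by(.data$population) |>
    dplyr::reframe(sample = sprintf("%s_%03d", .data$population,
                                    seq_len(.data$n)),
                   group = .data$group) |>
    select("sample", "population", "group") |>
    arrange(.data$sample)
  n_samp <- nrow(samples)
  outlier_samples <- sample(samples$sample, cfg$n_outlier_samples)

  ## true CNVRs --------------------------------------------------------
  lens <- pmax(1200, round(rlnorm(cfg$n_true_cnvrs, cfg$cnvr_meanlog,
                                  cfg$cnvr_sdlog)))
  min_gap <- 2 * cfg$flank + 1000
  truth <- .place_disjoint(lens, layout, min_gap) |>
    arrange(.data$chrom, .data$start) |>
    mutate(cnvr_id = sprintf("t%04d", row_number()),
           taggable = runif(n()) < cfg$fraction_taggable,
           selected = runif(n()) < cfg$fraction_selected,
           type = ifelse(.data$taggable,
                         sample(c("del", "ins"), n(), replace = TRUE),
                         sample(c("del", "ins", "mixed"), n(),
                                replace = TRUE, prob = c(.35, .35, .3))))

  ## per-population allele frequencies (hierarchical Balding-Nichols) ---
  q0 <- pmin(pmax(rbeta(nrow(truth), cfg$freq_beta[1], cfg$freq_beta[2]),
                  0.01), 0.9)
  groups <- unique(pops$group)
  q_group <- sapply(groups, function(g) .bn_draw(q0, cfg$group_divergence))
  truth_freq <- list_rbind(map(seq_len(nrow(pops)), function(i) {
    g <- pops$group[i]
    tibble(cnvr_id = truth$cnvr_id, population = pops$population[i],
           q = .bn_draw(q_group[, g], cfg$pop_divergence))
  }))

  ## LD blocks: taggable CNVR windows are blocks of their own -----------
  tag_windows <- truth |>
    filter(.data$taggable) |>
    mutate(start = pmax(0, .data$start - cfg$flank),
           end = pmin(layout$length[match(.data$chrom, layout$chrom)],
                      .data$end + cfg$flank)) |>
    select("chrom", "start", "end", tag_cnvr = "cnvr_id")
  blocks <- list_rbind(map(seq_len(nrow(layout)), function(ci) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    tw <- filter(tag_windows, .data$chrom == ch) |> arrange(.data$start)
    edges <- sort(unique(c(0, len, tw$start, tw$end)))
    gaps <- tibble(start = utils::head(edges, -1), end = edges[-1])
    list_rbind(map(seq_len(nrow(gaps)), function(gi) {
      s <- gaps$start[gi]; e <- gaps$end[gi]
      hit <- which(tw$start <= s & tw$end >= e)
      if (length(hit) == 1) {
        tibble(chrom = ch, start = s, end = e, tag_cnvr = tw$tag_cnvr[hit])
      } else {
        cuts <- unique(c(seq(s, e, by = cfg$block_bp), e))
        tibble(chrom = ch, start = utils::head(cuts, -1), end = cuts[-1],
               tag_cnvr = NA_character_)
      }
    }))
  })) |>
    filter(.data$end > .data$start) |>
    mutate(block_id = row_number())

  ## SNP sites ----------------------------------------------------------
  sites <- list_rbind(map(seq_len(nrow(layout)), function(ci) {
    pos0 <- seq(round(cfg$snp_spacing / 2), layout$length[ci] - 1,
                by = cfg$snp_spacing)
    tibble(chrom = layout$chrom[ci], pos0 = pos0)
  })) |>
    mutate(pos = .data$pos0 + 1,
           ref = sample(c("A", "C", "G", "T"), n(), replace = TRUE))
  alt_of <- c(A = "G", C = "T", G = "A", T = "C")
  sites$alt <- unname(alt_of[sites$ref])
  # block membership per SNP
  bp <- overlap_pairs(blocks, tibble(chrom = sites$chrom,
                                     start = sites$pos0,
                                     end = sites$pos0 + 1))
  site_block <- integer(nrow(sites))
  site_block[bp$b_row] <- blocks$block_id[bp$a_row]

  ## founder mosaic haplotypes ------------------------------------------
  n_chrom <- 2 * n_samp
  chrom_pop <- rep(samples$population, each = 2)
  K <- cfg$founder_pool
  haps <- matrix(NA_integer_, nrow(sites), n_chrom)
  tag_dosage <- list() # cnvr_id -> per-chromosome carrier indicator
  for (b in seq_len(nrow(blocks))) {
    idx <- which(site_block == blocks$block_id[b])
    tag_id <- blocks$tag_cnvr[b]
    founders <- if (length(idx) > 0) {
      f_s <- runif(length(idx), 0.15, 0.85)
      matrix(rbinom(length(idx) * K, 1, rep(f_s, K)), ncol = K)
    } else matrix(integer(0), 0, K)
    if (!is.na(tag_id) && length(idx) >= 4) {
      # variants private to the CNV's ancestral background: mutations that
      # accumulated on the founder haplotype since the CNV arose
      mark <- sample(length(idx), 3)
      founders[mark, ] <- 0L
      founders[mark, 1] <- 1L
    }
    assign_b <- integer(n_chrom)
    for (p in pops$population) {
      cols <- which(chrom_pop == p)
      if (!is.na(tag_id)) {
        qv <- truth_freq$q[truth_freq$cnvr_id == tag_id &
                             truth_freq$population == p]
        w_rest <- runif(K - 1); w_rest <- w_rest / sum(w_rest)
        pr <- c(qv, (1 - qv) * w_rest)
      } else {
        pr <- runif(K, 0.2, 1); pr <- pr / sum(pr)
      }
      assign_b[cols] <- sample.int(K, length(cols), replace = TRUE,
                                   prob = pr)
    }
    if (length(idx) > 0) haps[idx, ] <- founders[, assign_b]
    if (!is.na(tag_id)) {
      tag_dosage[[tag_id]] <- as.integer(assign_b == 1L)
      if (length(idx) >= 2) {
        attr(tag_dosage[[tag_id]], "alleles") <-
          paste(founders[, 1], collapse = "")
        attr(tag_dosage[[tag_id]], "positions") <- sites$pos0[idx]
      }
    }
  }

  ## true copy states ---------------------------------------------------
  sample_of_chrom <- rep(samples$sample, each = 2)
  copy_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    id <- truth$cnvr_id[i]
    if (truth$taggable[i]) {
      carrier <- tag_dosage[[id]]
    } else {
      qv <- truth_freq$q[truth_freq$cnvr_id == id]
      names(qv) <- truth_freq$population[truth_freq$cnvr_id == id]
      carrier <- rbinom(n_chrom, 1, qv[chrom_pop])
    }
    sign <- switch(truth$type[i],
                   del = -1L, ins = 1L,
                   mixed = sample(c(-1L, 1L), n_chrom, replace = TRUE))
    delta <- tapply(carrier * sign, sample_of_chrom, sum)
    copy <- pmax(0, 2 + as.integer(delta[samples$sample]))
    hit <- which(copy != 2)
    if (length(hit) > 0) {
      copy_rows[[i]] <- tibble(cnvr_id = id, sample = samples$sample[hit],
                               copy_number = copy[hit])
    }
  }
  truth_copies <- list_rbind(copy_rows[!vapply(copy_rows, is.null,
                                               logical(1))])
  truth$tag_alleles <- map_chr(truth$cnvr_id, function(id) {
    d <- tag_dosage[[id]]
    if (is.null(d)) NA_character_ else attr(d, "alleles") %||% NA_character_
  })

  ## caller A (fine) ----------------------------------------------------
  jitter_call <- function(rows, sd_bp, frac_sd, caller) {
    lens_chr <- setNames(layout$length, layout$chrom)
    s <- rows$start + round(rnorm(nrow(rows), 0, sd_bp))
    e <- rows$end + round(rnorm(nrow(rows), 0, sd_bp))
    s <- pmax(0, pmin(s, rows$end - 1))
    e <- pmin(lens_chr[rows$chrom], pmax(e, s + 1))
    tibble(chrom = rows$chrom, start = s, end = e, sample = rows$sample,
           copy_number = rows$copy_number,
           fractional_copy = pmax(0, rows$copy_number +
                                    rnorm(nrow(rows), 0, frac_sd)),
           caller = caller)
  }
  a_rows <- truth_copies |>
    left_join(select(truth, "cnvr_id", "chrom", "start", "end"),
              by = "cnvr_id")
  calls_a <- jitter_call(a_rows, cfg$caller_a_jitter_sd,
                         cfg$caller_a_frac_sd, "callerA")

  ## false positives: each caller has its own FP process; outlier
  ## samples get the multiplied rate in both
  fp_mean <- cfg$fp_rate * cfg$n_true_cnvrs
  fp_calls <- function(caller, meanlog) {
    n_fp <- rpois(n_samp, fp_mean *
                    ifelse(samples$sample %in% outlier_samples,
                           cfg$outlier_fp_multiplier, 1))
    if (sum(n_fp) == 0) return(NULL)
    fp_len <- pmin(pmax(1200, round(rlnorm(sum(n_fp), meanlog,
                                           cfg$cnvr_sdlog))),
                   max(layout$length))
    fp_int <- place_random(fp_len, layout)
    fp_cn <- sample(c(1L, 3L), sum(n_fp), replace = TRUE)
    tibble(
      chrom = fp_int$chrom, start = fp_int$start, end = fp_int$end,
      sample = rep(samples$sample, n_fp), copy_number = fp_cn,
      fractional_copy = pmax(0, fp_cn + rnorm(sum(n_fp), 0,
                                              cfg$caller_a_frac_sd)),
      caller = caller)
  }
  calls_a <- bind_rows(calls_a, fp_calls("callerA", cfg$cnvr_meanlog))

  ## caller B (coarse): true CNVRs within merge_distance become one ----
  tr_sorted <- arrange(truth, .data$chrom, .data$start)
  nt <- nrow(tr_sorted)
  gap_new <- c(TRUE, tr_sorted$chrom[-1] != tr_sorted$chrom[-nt] |
                 tr_sorted$start[-1] - tr_sorted$end[-nt] >
                 cfg$caller_b_merge_distance)
  tr_sorted$b_cluster <- cumsum(gap_new)
  b_regions <- tr_sorted |>
    group_by(.data$b_cluster) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  member_of <- setNames(tr_sorted$b_cluster, tr_sorted$cnvr_id)
  b_rows <- truth_copies |>
    mutate(b_cluster = member_of[.data$cnvr_id],
           len = truth$end[match(.data$cnvr_id, truth$cnvr_id)] -
             truth$start[match(.data$cnvr_id, truth$cnvr_id)]) |>
    group_by(.data$b_cluster, .data$sample) |>
    arrange(dplyr::desc(.data$len)) |>
    summarise(copy_number = first(.data$copy_number), .groups = "drop") |>
    left_join(b_regions, by = "b_cluster")
  calls_b <- jitter_call(b_rows, cfg$caller_b_jitter_sd,
                         cfg$caller_a_frac_sd, "callerB")
  # coarse-caller FPs are longer, mirroring its region granularity
  calls_b <- bind_rows(calls_b,
                       fp_calls("callerB", cfg$cnvr_meanlog + log(6)))

  ## missing genotypes --------------------------------------------------
  if (cfg$missing_rate > 0) {
    n_geno <- nrow(sites) * n_samp
    miss <- which(runif(n_geno) < cfg$missing_rate)
    if (length(miss) > 0) {
      si <- ((miss - 1) %% nrow(sites)) + 1
      sj <- ((miss - 1) %/% nrow(sites)) + 1
      haps[cbind(si, 2 * sj - 1)] <- NA_integer_
      haps[cbind(si, 2 * sj)] <- NA_integer_
    }
  }
  snps <- phased_snps(select(sites, "chrom", "pos", "ref", "alt"),
                      haps, samples$sample)

  ## selection scores ---------------------------------------------------
  sel_regions <- truth |>
    filter(.data$selected) |>
    flank_regions(layout, cfg$flank)
  pts <- tibble(chrom = sites$chrom, start = sites$pos0,
                end = sites$pos0 + 1)
  enriched <- overlaps_any(pts, sel_regions)
  u <- runif(nrow(sites))
  u[enriched] <- u[enriched] / cfg$selection_enrichment
  scores <- tibble(chrom = sites$chrom, pos = sites$pos,
                   score = -log10(pmax(u, 1e-300)), pos0 = sites$pos0)

  ## known-region database ----------------------------------------------
  n_known <- round(cfg$known_db_coverage * nrow(truth))
  kn_idx <- sample(nrow(truth), n_known)
  pad1 <- round(runif(n_known, 0, 2000))
  pad2 <- round(runif(n_known, 0, 2000))
  known <- tibble(
    chrom = truth$chrom[kn_idx],
    start = pmax(0, truth$start[kn_idx] - pad1),
    end = pmin(layout$length[match(truth$chrom[kn_idx], layout$chrom)],
               truth$end[kn_idx] + pad2)) |>
    arrange(.data$chrom, .data$start)

  structure(list(
    truth = select(truth, "cnvr_id", "chrom", "start", "end", "type",
                   "taggable", "selected", "tag_alleles"),
    truth_freq = truth_freq, truth_copies = truth_copies,
    calls_a = calls_a, calls_b = calls_b, snps = snps, scores = scores,
    known = known, samples = samples, outlier_samples = outlier_samples,
    layout = layout, config = cfg),
    class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat("<cnv_cohort> ", nrow(x$truth), " true CNVRs, ", nrow(x$samples),
      " samples, ", nrow(x$snps$sites), " SNPs (seed ", x$config$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the flat formats the readers consume: caller BEDs, a
#' phased VCF, score/sample/genome TSVs and the known-region BED.
#'
#' @param cohort A `cnv_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cohort$config$seed
  paths <- c(
    calls_a = file.path(dir, "caller_a.bed"),
    calls_b = file.path(dir, "caller_b.bed"),
    snps = file.path(dir, "snps.vcf"),
    scores = file.path(dir, "scores.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genome = file.path(dir, "genome.tsv"),
    known = file.path(dir, "known.bed"),
    truth = file.path(dir, "truth.tsv"))
  write_calls(cohort$calls_a, paths["calls_a"], seed = seed)
  write_calls(cohort$calls_b, paths["calls_b"], seed = seed)
  write_vcf_phased(cohort$snps, paths["snps"], seed = seed)
  write_tsv_commented(select(cohort$scores, "chrom", "pos", "score"),
                      paths["scores"], seed = seed)
  write_tsv_commented(cohort$samples, paths["samples"], seed = seed)
  write_tsv_commented(cohort$layout, paths["genome"], seed = seed)
  write_bed(cohort$known, paths["known"], seed = seed)
  write_tsv_commented(cohort$truth, paths["truth"], seed = seed)
  invisible(paths)
}
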