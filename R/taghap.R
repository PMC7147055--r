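# Tag-haplotype engine: assemble phased SNP haplotypes near CNVR boundaries
# from LD blocks (single-linkage over pairwise r-squared), then regress each
# sample's fractional copy number on haplotype dosage (0/1/2). A CNVR is
# "tagged" when at least one haplotype survives a per-CNVR Bonferroni
# correction at alpha.

#' Linkage disequilibrium r-squared between two phased SNPs
#'
#' Squared Pearson correlation of the per-chromosome allele indicators.
#' Phase is known, so no EM frequency estimation is needed; missing
#' chromosomes are excluded pairwise.
#'
#' @param a,b Integer vectors of 0/1 allele indices, one entry per
#'   chromosome (2 per sample), NA = missing.
#' @return r-squared in `[0, 1]`, or NA if either SNP is monomorphic on the
#'   pairwise-complete chromosomes or fewer than 4 of them remain.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 4) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# r-squared matrix for all SNPs in a phased_snps object (pairwise-complete
# chromosomes); monomorphic columns give NA rows/columns.
.ld_r2_matrix <- function(snps) {
  m <- t(snps$haps) # chromosomes x snps
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
}

#' Candidate SNP window around a CNVR
#'
#' The CNVR interval extended by `flank` bp on each side, clipped to the
#' chromosome.
#'
#' @param chrom,start,end CNVR interval (0-based half-open).
#' @param layout Genome layout.
#' @param flank Flank width in bp (default 5000).
#' @return One-row interval tibble.
#' @export
candidate_window <- function(chrom, start, end, layout, flank = 5000) {
  len <- layout$length[match(chrom, layout$chrom)]
  if (is.na(len)) abort(paste0("unknown chromosome: ", chrom))
  tibble(chrom = chrom, start = max(0, start - flank),
         end = min(len, end + flank))
}

#' Assemble haplotypes from SNPs in LD
#'
#' (1) r-squared is computed for every SNP pair at most `ld_window` bp
#' apart; (2) SNPs joined by any edge with r-squared above `r2_threshold`
#' are clustered by single linkage (connected components); (3) singleton
#' clusters are dropped (a tag SNP must be in LD with at least one other);
#' (4) within each cluster, every distinct complete per-chromosome allele
#' string observed in the cohort defines one haplotype, and a sample's
#' dosage is the number of its two chromosomes matching the string exactly.
#' Haplotypes observed on fewer than `min_chrom` chromosomes are dropped as
#' noise.
#'
#' @param snps A `phased_snps` object (typically a candidate window).
#' @param r2_threshold LD threshold (default 0.8, strict inequality).
#' @param ld_window Maximum pair distance in bp (default 50000).
#' @param min_chrom Minimum chromosomes carrying a haplotype (default 2).
#' @return List: `haplotypes` (tibble: `hap_id`, `cluster`, `n_snps`,
#'   `positions` list-column, `alleles` string, `n_chrom`) and `dosage`
#'   (matrix: haplotypes x samples).
#' @export
build_haplotypes <- function(snps, r2_threshold = 0.8, ld_window = 50000,
                             min_chrom = 2) {
  empty <- list(
    haplotypes = tibble(hap_id = character(), cluster = integer(),
                        n_snps = integer(), positions = list(),
                        alleles = character(), n_chrom = integer()),
    dosage = matrix(0, 0, length(snps$samples),
                    dimnames = list(NULL, snps$samples)))
  poly <- apply(snps$haps, 1, function(z) {
    z <- z[!is.na(z)]
    length(z) > 0 && var(z) > 0
  })
  snps <- phased_snps(snps$sites[poly, ], snps$haps[poly, , drop = FALSE],
                      snps$samples)
  p <- nrow(snps$sites)
  if (p < 2) return(empty)
  r2 <- .ld_r2_matrix(snps)
  pos <- snps$sites$pos0
  near <- abs(outer(pos, pos, "-")) <= ld_window
  adj <- !is.na(r2) & r2 > r2_threshold & near
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  keep_clusters <- as.integer(names(sizes)[sizes >= 2])
  if (length(keep_clusters) == 0) return(empty)

  samples <- snps$samples
  hap_rows <- list()
  dosage_rows <- list()
  for (cl in keep_clusters) {
    idx <- which(comp == cl)
    sub <- snps$haps[idx, , drop = FALSE]
    strings <- apply(sub, 2, function(col) {
      if (anyNA(col)) NA_character_ else paste(col, collapse = "")
    })
    tab <- table(strings, useNA = "no")
    tab <- tab[tab >= min_chrom]
    if (length(tab) == 0) next
    s1 <- strings[seq(1, length(strings), by = 2)]
    s2 <- strings[seq(2, length(strings), by = 2)]
    for (j in seq_along(tab)) {
      al <- names(tab)[j]
      hid <- paste0("c", cl, "_h", j)
      hap_rows[[hid]] <- tibble(
        hap_id = hid, cluster = cl, n_snps = length(idx),
        positions = list(pos[idx]), alleles = al,
        n_chrom = as.integer(tab[j]))
      dosage_rows[[hid]] <- (!is.na(s1) & s1 == al) + (!is.na(s2) & s2 == al)
    }
  }
  if (length(hap_rows) == 0) return(empty)
  dosage <- do.call(rbind, dosage_rows)
  colnames(dosage) <- samples
  list(haplotypes = list_rbind(unname(hap_rows)), dosage = dosage)
}

#' Is a haplotype informative about copy number?
#'
#' A haplotype whose carriers (dosage > 0) all share one integer copy number
#' is uninformative: it cannot discriminate copy states and is excluded from
#' regression and from the Bonferroni denominator. A haplotype with constant
#' dosage across all samples is likewise uninformative.
#'
#' @param dosage Numeric dosage vector (0/1/2) over samples.
#' @param copy_number Integer copy numbers over the same samples.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
informative_filter <- function(dosage, copy_number) {
  carriers <- which(dosage > 0 & !is.na(copy_number))
  if (length(carriers) == 0) {
    abort("haplotype with zero carriers should not exist after assembly")
  }
  if (var(dosage, na.rm = TRUE) == 0) return(FALSE)
  length(unique(copy_number[carriers])) > 1
}

#' Regress fractional copy number on haplotype dosage
#'
#' Ordinary least squares of fractional copy on dosage; the p-value is a
#' two-sided t-test of zero slope with n - 2 degrees of freedom.
#'
#' @param dosage Numeric dosage vector (0/1/2).
#' @param fractional_copy Numeric fractional copy numbers.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_slope`,
#'   `n`.
#' @export
copy_regression <- function(dosage, fractional_copy) {
  ok <- !is.na(dosage) & !is.na(fractional_copy)
  x <- dosage[ok]; y <- fractional_copy[ok]
  n <- length(x)
  if (n < 3) abort("regression needs at least 3 complete samples")
  if (var(x) == 0) abort("constant dosage: filter uninformative haplotypes first")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(resid^2) / sst
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  p <- if (se == 0) 0 else 2 * pt(abs(slope / se), df = n - 2,
                                  lower.tail = FALSE)
  tibble(slope = slope, intercept = intercept, r_squared = r2,
         p_slope = p, n = n)
}

#' Tag CNVRs with SNP haplotypes
#'
#' Runs the full chain for every CNVR: candidate window (+/- `flank`),
#' haplotype assembly from LD clusters, informative-haplotype filter, copy
#' regression, and a per-CNVR Bonferroni correction over the number of
#' informative haplotypes tested. A CNVR is tagged iff at least one
#' haplotype reaches `p_adjusted < alpha`.
#'
#' @param cnvrs A [cnvr_set()] with fractional copies.
#' @param snps A QC'd `phased_snps` object on the same cohort.
#' @param layout Genome layout.
#' @param flank Candidate-window flank in bp (default 5000).
#' @param ld_window Maximum LD pair distance in bp (default 50000).
#' @param r2_threshold LD clustering threshold (default 0.8).
#' @param alpha Family-wise significance level after Bonferroni (default
#'   0.05).
#' @param include_interior Include SNPs inside the CNVR itself (default
#'   TRUE); set FALSE to use flanks only, e.g. when interior SNP calls are
#'   unreliable inside deletions.
#' @param samples Optional sample roster; when given, per-population tagging
#'   is re-run on each population's samples.
#' @return Object of class `tag_result`: `associations` (one row per tested
#'   haplotype), `cnvrs` (per-CNVR tagged flag), optionally
#'   `per_population`.
#' @export
tag_cnvrs <- function(cnvrs, snps, layout, flank = 5000, ld_window = 50000,
                      r2_threshold = 0.8, alpha = 0.05,
                      include_interior = TRUE, samples = NULL) {
  regions <- cnvrs$regions
  run_one_cohort <- function(snps_sub, copies_sub) {
    assoc <- vector("list", nrow(regions))
    flags <- logical(nrow(regions))
    nhap <- integer(nrow(regions))
    ninf <- integer(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i, ]
      win <- candidate_window(rg$chrom, rg$start, rg$end, layout, flank)
      sub <- snp_subset(snps_sub, win$chrom, win$start, win$end)
      if (!include_interior) {
        keep <- sub$sites$pos0 < rg$start | sub$sites$pos0 >= rg$end
        sub <- phased_snps(sub$sites[keep, ],
                           sub$haps[keep, , drop = FALSE], sub$samples)
      }
      hb <- build_haplotypes(sub, r2_threshold = r2_threshold,
                             ld_window = ld_window)
      nhap[i] <- nrow(hb$haplotypes)
      if (nrow(hb$haplotypes) == 0) next
      frac <- .fractional_vector(copies_sub, rg$cnvr_id, snps_sub$samples)
      cn <- round(frac)
      inf <- vapply(seq_len(nrow(hb$haplotypes)), function(j) {
        informative_filter(hb$dosage[j, ], cn)
      }, logical(1))
      m <- sum(inf)
      ninf[i] <- m
      if (m == 0) next
      rows <- map(which(inf), function(j) {
        fit <- copy_regression(hb$dosage[j, ], frac)
        dplyr::bind_cols(
          tibble(cnvr_id = rg$cnvr_id, hap_id = hb$haplotypes$hap_id[j],
                 n_snps = hb$haplotypes$n_snps[j],
                 alleles = hb$haplotypes$alleles[j],
                 positions = hb$haplotypes$positions[j]),
          fit)
      })
      tab <- list_rbind(rows) |>
        mutate(n_tested = m,
               p_adjusted = pmin(1, .data$p_slope * m),
               significant = .data$p_adjusted < alpha)
      assoc[[i]] <- tab
      flags[i] <- any(tab$significant)
    }
    list(associations = list_rbind(assoc[!vapply(assoc, is.null, logical(1))]),
         cnvrs = tibble(cnvr_id = regions$cnvr_id, n_haplotypes = nhap,
                        n_informative = ninf, tagged = flags))
  }
  full <- run_one_cohort(snps, cnvrs$copies)
  per_pop <- NULL
  if (!is.null(samples)) {
    pops <- sort(unique(samples$population))
    per_pop <- list_rbind(map(pops, function(p) {
      ids <- intersect(samples$sample[samples$population == p], snps$samples)
      cols <- rep(match(ids, snps$samples) * 2, each = 2) - c(1, 0)
      sub <- phased_snps(snps$sites, snps$haps[, cols, drop = FALSE], ids)
      res <- run_one_cohort(sub, filter(cnvrs$copies, .data$sample %in% ids))
      mutate(res$cnvrs, population = p, .before = 1)
    }))
  }
  structure(list(associations = full$associations, cnvrs = full$cnvrs,
                 per_population = per_pop,
                 params = list(flank = flank, ld_window = ld_window,
                               r2_threshold = r2_threshold, alpha = alpha,
                               include_interior = include_interior)),
            class = "tag_result")
}

# Fractional copy vector for one CNVR over an ordered sample vector;
# samples without a call sit at the diploid reference 2.
.fractional_vector <- function(copies, id, samples) {
  sub <- copies[copies$cnvr_id == id, ]
  out <- rep(2, length(samples))
  hit <- match(sub$sample, samples)
  ok <- !is.na(hit)
  out[hit[ok]] <- sub$fractional_copy[ok]
  out
}

#' @export
print.tag_result <- function(x, ...) {
  cat("<tag_result> ", sum(x$cnvrs$tagged), " of ", nrow(x$cnvrs),
      " CNVRs tagged; ", nrow(x$associations), " haplotype associations\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy tag_result
tidy.tag_result <- function(x, ...) {
  select(x$associations, -"positions")
}

#' @export
#' @method glance tag_result
glance.tag_result <- function(x, ...) {
  tibble(n_cnvrs = nrow(x$cnvrs), n_tagged = sum(x$cnvrs$tagged),
         tagged_fraction = mean(x$cnvrs$tagged),
         n_haplotypes_tested = nrow(x$associations),
         n_significant = sum(x$associations$significant %||% logical(0)))
}
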