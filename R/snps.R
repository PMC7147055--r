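# Phased biallelic SNPs are held as a compact haplotype matrix: one row per
# site, two columns per sample (chromosome copies in phase order), entries
# 0/1 allele indices with NA for missing. This is the shape every LD and
# haplotype operation wants.

#' Construct a phased SNP set
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param haps Integer matrix, `nrow(sites)` x `2 * length(samples)`, of 0/1
#'   allele indices (NA = missing). Columns are sample chromosomes in order:
#'   sample1 hapA, sample1 hapB, sample2 hapA, ...
#' @param samples Character vector of sample ids.
#' @return An object of class `phased_snps`.
#' @export
phased_snps <- function(sites, haps, samples) {
  stopifnot(nrow(haps) == nrow(sites), ncol(haps) == 2 * length(samples))
  sites <- as_tibble(sites)
  if (!"pos0" %in% names(sites)) sites$pos0 <- sites$pos - 1
  vals <- haps[!is.na(haps)]
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L))) {
    abort("haplotype matrix entries must be 0, 1 or NA (biallelic only)")
  }
  colnames(haps) <- paste0(rep(samples, each = 2), "_", rep(1:2, length(samples)))
  structure(list(sites = sites, haps = haps, samples = samples),
            class = "phased_snps")
}

#' @export
print.phased_snps <- function(x, ...) {
  cat("<phased_snps> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples (", sum(is.na(x$haps)), " missing alleles)\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy phased_snps
tidy.phased_snps <- function(x, ...) x$sites

#' Subset a phased SNP set to a half-open window
#'
#' A 1-based SNP position p is inside `[start, end)` iff `start < p <= end`.
#'
#' @param snps A `phased_snps` object.
#' @param chrom Chromosome label.
#' @param start,end 0-based half-open window.
#' @return A `phased_snps` object restricted to the window.
#' @export
snp_subset <- function(snps, chrom, start, end) {
  keep <- snps$sites$chrom == chrom & snps$sites$pos0 >= start &
    snps$sites$pos0 < end
  phased_snps(snps$sites[keep, ], snps$haps[keep, , drop = FALSE],
              snps$samples)
}

#' Read phased genotypes from a VCF
#'
#' Reads the GT-only subset of VCF 4.x used by the pipeline: biallelic SNPs
#' with `|`-phased genotypes. Multiallelic sites are rejected. Missing
#' genotypes (`.|.` or `./.`) are flagged as NA, never imputed.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param allow_unphased If `TRUE`, `/`-separated genotypes are accepted and
#'   treated as phased in file order; the default is to error, because every
#'   downstream haplotype operation assumes real phase.
#' @return A `phased_snps` object.
#' @export
read_vcf_phased <- function(path, allow_unphased = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multiallelic sites present; this reader is biallelic-only")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  samples <- colnames(gt)
  unphased <- grepl("/", gt, fixed = TRUE) & !grepl("\\./\\.", gt)
  if (any(unphased, na.rm = TRUE) && !allow_unphased) {
    row1 <- ((which(unphased)[1] - 1) %% nrow(gt)) + 1
    abort(paste0("unphased '/' genotype found (e.g. site row ", row1,
                 "); rerun with allow_unphased = TRUE to accept file order ",
                 "as phase"))
  }
  alle <- function(k) {
    a <- sub(paste0("^([^/|]*)[/|]([^/|]*).*$"), paste0("\\", k), gt)
    a[a == "." | is.na(a) | a == ""] <- NA
    suppressWarnings(matrix(as.integer(a), nrow = nrow(gt)))
  }
  a1 <- alle(1)
  a2 <- alle(2)
  # either allele unparseable -> whole genotype missing
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA
  a2[miss] <- NA
  haps <- matrix(NA_integer_, nrow(gt), 2 * length(samples))
  haps[, seq(1, ncol(haps), by = 2)] <- a1
  haps[, seq(2, ncol(haps), by = 2)] <- a2
  sites <- tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                  ref = fix$REF, alt = fix$ALT)
  phased_snps(sites, haps, samples)
}

#' Write phased genotypes as VCF
#'
#' Emits the minimal GT-only VCF 4.2 subset that [read_vcf_phased()] reads.
#'
#' @param snps A `phased_snps` object.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_phased <- function(snps, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=cnvrpipe",
                      as.character(packageVersion("cnvrpipe")),
                      if (!is.null(seed)) paste0(";seed=", seed) else ""),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", snps$samples), collapse = "\t")),
             con)
  n <- nrow(snps$sites)
  if (n > 0) {
    h <- snps$haps
    hc <- matrix(as.character(h), nrow = n)
    hc[is.na(hc)] <- "."
    gt <- matrix(paste(hc[, seq(1, ncol(hc), by = 2)],
                       hc[, seq(2, ncol(hc), by = 2)], sep = "|"),
                 nrow = n)
    lines <- paste(snps$sites$chrom,
                   format(snps$sites$pos, scientific = FALSE, trim = TRUE),
                   ".", snps$sites$ref, snps$sites$alt, ".", "PASS", ".",
                   "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

# Per-locus genotype counts (AA, Aa, aa by alt-allele dosage) over
# non-missing samples.
.geno_counts <- function(snps) {
  h <- snps$haps
  a1 <- h[, seq(1, ncol(h), by = 2), drop = FALSE]
  a2 <- h[, seq(2, ncol(h), by = 2), drop = FALSE]
  dos <- a1 + a2
  cbind(n0 = rowSums(dos == 0, na.rm = TRUE),
        n1 = rowSums(dos == 1, na.rm = TRUE),
        n2 = rowSums(dos == 2, na.rm = TRUE))
}

#' Hardy-Weinberg goodness-of-fit p-values
#'
#' One-degree-of-freedom chi-square of observed genotype counts against
#' Hardy-Weinberg expectations at the observed allele frequency. Monomorphic
#' loci get p = 1 (nothing to test).
#'
#' @param snps A `phased_snps` object.
#' @return Numeric vector of p-values, one per site.
#' @export
hwe_pvalues <- function(snps) {
  gc <- .geno_counts(snps)
  n <- rowSums(gc)
  p <- (2 * gc[, "n2"] + gc[, "n1"]) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  stat <- (gc[, "n0"] - e0)^2 / pmax(e0, .Machine$double.eps) +
    (gc[, "n1"] - e1)^2 / pmax(e1, .Machine$double.eps) +
    (gc[, "n2"] - e2)^2 / pmax(e2, .Machine$double.eps)
  out <- pchisq(stat, df = 1, lower.tail = FALSE)
  out[n == 0 | p == 0 | p == 1] <- 1
  unname(out)
}

#' SNP and sample quality control
#'
#' Applies the three QC steps in a fixed order: (1) drop loci with more than
#' `max_locus_missing` missing genotypes; (2) drop samples with more than
#' `max_sample_missing` missing genotypes over the surviving loci; (3) drop
#' loci failing the Hardy-Weinberg goodness-of-fit test at `p < hwe_alpha`.
#'
#' @param snps A `phased_snps` object.
#' @param max_locus_missing Maximum tolerated per-locus missing fraction.
#' @param max_sample_missing Maximum tolerated per-sample missing fraction.
#' @param hwe_alpha Hardy-Weinberg rejection level.
#' @return List with `snps` (filtered `phased_snps`) and `report` (tibble of
#'   counts removed at each step).
#' @export
snp_qc <- function(snps, max_locus_missing = 0.10, max_sample_missing = 0.10,
                   hwe_alpha = 0.01) {
  if (nrow(snps$sites) == 0) abort("no SNP records to QC")
  n_samp0 <- length(snps$samples)
  h <- snps$haps
  gmiss <- is.na(h[, seq(1, ncol(h), by = 2), drop = FALSE])
  locus_miss <- rowMeans(gmiss)
  keep_loci <- locus_miss <= max_locus_missing
  s1 <- phased_snps(snps$sites[keep_loci, ],
                    snps$haps[keep_loci, , drop = FALSE], snps$samples)

  h1 <- s1$haps
  gm1 <- is.na(h1[, seq(1, ncol(h1), by = 2), drop = FALSE])
  samp_miss <- if (nrow(gm1) > 0) colMeans(gm1) else rep(0, n_samp0)
  keep_samp <- samp_miss <= max_sample_missing
  cols <- rep(keep_samp, each = 2)
  s2 <- phased_snps(s1$sites, s1$haps[, cols, drop = FALSE],
                    s1$samples[keep_samp])

  hwe_p <- hwe_pvalues(s2)
  keep_hwe <- hwe_p >= hwe_alpha
  s3 <- phased_snps(s2$sites[keep_hwe, ], s2$haps[keep_hwe, , drop = FALSE],
                    s2$samples)

  report <- tibble(
    step = c("locus_missingness", "sample_missingness", "hwe"),
    removed = c(sum(!keep_loci), sum(!keep_samp), sum(!keep_hwe)),
    remaining_loci = c(nrow(s1$sites), nrow(s2$sites), nrow(s3$sites)),
    remaining_samples = c(n_samp0, length(s2$samples), length(s3$samples))
  )
  if (nrow(s3$sites) == 0) {
    warn("SNP QC removed every locus; downstream haplotype stages will be empty")
  }
  list(snps = s3, report = report)
}
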