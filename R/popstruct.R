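# Population structure from CNV genotypes: the multi-allelic allele-pair
# encoding of copy number, PCA / IBS-MDS of the copy matrix, and
# Weir-Cockerham F_ST restricted to bi-allelic deletions (the only loci
# where the phase of the CNV genotype is unambiguous).

#' Encode an integer copy number as an allele pair
#'
#' Copies are split as evenly as possible between the two chromosomes and
#' shifted so the allele labels are 1-4: 0 copies -> (1,1), 1 -> (1,2),
#' 2 -> (2,2), 3 -> (2,3), 4 -> (3,3), 5 -> (3,4), and six or more copies
#' cap at (4,4). Decoding returns `min(copy, 6)`.
#'
#' @param copy_number Non-negative integer vector.
#' @return Tibble with columns `a1 <= a2` (alleles in 1..4).
#' @examples
#' encode_alleles(c(0, 1, 3, 7)) # (1,1) (1,2) (2,3) (4,4)
#' @export
encode_alleles <- function(copy_number) {
  if (any(copy_number < 0 | copy_number != floor(copy_number))) {
    abort("copy numbers must be non-negative integers")
  }
  c6 <- pmin(copy_number, 6)
  tibble(a1 = 1 + floor(c6 / 2), a2 = 1 + ceiling(c6 / 2))
}

#' Decode an allele pair back to a copy number
#'
#' @param a1,a2 Allele labels in 1..4.
#' @return Integer copies, `(a1 - 1) + (a2 - 1)`.
#' @export
decode_alleles <- function(a1, a2) {
  (a1 - 1) + (a2 - 1)
}

#' Per-sample copy-number matrix of a CNVR set
#'
#' Samples x CNVRs integer matrix; samples without a call at a CNVR sit at
#' the diploid reference 2.
#'
#' @param cnvrs A [cnvr_set()].
#' @param samples Optional sample id vector fixing row order; defaults to
#'   the samples seen in the copy table.
#' @return Integer matrix with sample rownames and CNVR-id colnames.
#' @export
copy_matrix <- function(cnvrs, samples = NULL) {
  ids <- samples %||% sort(unique(cnvrs$copies$sample))
  regions <- cnvrs$regions$cnvr_id
  m <- matrix(2, nrow = length(ids), ncol = length(regions),
              dimnames = list(ids, regions))
  cp <- filter(cnvrs$copies, .data$sample %in% ids)
  m[cbind(match(cp$sample, ids), match(cp$cnvr_id, regions))] <- cp$copy_number
  m
}

#' Principal component analysis of the copy-number matrix
#'
#' PCA of the column-centred copy matrix after dropping zero-variance loci.
#' For parity with identity-by-state pipelines, [ibs_mds()] offers an MDS
#' over allele-pair sharing distances; the two give the same qualitative
#' structure.
#'
#' @param cnvrs A [cnvr_set()] or a samples x loci numeric matrix.
#' @param k Number of components to keep (default 10; reduced with a
#'   warning if it exceeds the matrix rank).
#' @param samples Optional roster tibble; population/group labels are joined
#'   onto the coordinates.
#' @return Object of class `cnv_pca`: `scores` tibble,
#'   `variance_explained`, `sdev`.
#' @export
cnv_pca <- function(cnvrs, k = 10, samples = NULL) {
  m <- if (inherits(cnvrs, "cnvr_set")) {
    copy_matrix(cnvrs, samples = samples$sample)
  } else as.matrix(cnvrs)
  if (nrow(m) < 2) abort("PCA needs at least 2 samples")
  keep <- apply(m, 2, var) > 0
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0) abort("no variable loci: PCA undefined")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (k > rank) {
    warn(paste0("k = ", k, " exceeds matrix rank ", rank, "; reduced"))
    k <- rank
  }
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE]) |>
    mutate(sample = rownames(m), .before = 1)
  if (!is.null(samples)) {
    scores <- left_join(scores, samples, by = "sample")
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, variance_explained = ve[seq_len(k)],
                 sdev = pc$sdev, k = k),
            class = "cnv_pca")
}

#' @export
print.cnv_pca <- function(x, ...) {
  cat("<cnv_pca> ", nrow(x$scores), " samples, ", x$k,
      " components (PC1 ", round(100 * x$variance_explained[1], 1),
      "% variance)\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy cnv_pca
tidy.cnv_pca <- function(x, ...) x$scores

#' @export
#' @method glance cnv_pca
glance.cnv_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_len(x$k)),
         variance_explained = x$variance_explained)
}

#' MDS over identity-by-state of allele-pair encoded copy numbers
#'
#' Copy numbers are encoded as allele pairs ([encode_alleles()]); the IBS
#' distance between two samples at one locus is
#' `(2 - shared alleles) / 2`, averaged over loci; classical MDS embeds the
#' resulting distance matrix.
#'
#' @param cnvrs A [cnvr_set()] or copy matrix.
#' @param k Embedding dimension (default 2).
#' @param samples Optional roster tibble joined onto coordinates.
#' @return Tibble: `sample`, `mds1`..`mdsk`.
#' @export
ibs_mds <- function(cnvrs, k = 2, samples = NULL) {
  m <- if (inherits(cnvrs, "cnvr_set")) {
    copy_matrix(cnvrs, samples = samples$sample)
  } else as.matrix(cnvrs)
  enc <- encode_alleles(as.integer(m))
  a1 <- matrix(enc$a1, nrow(m)); a2 <- matrix(enc$a2, nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- pmin(a1[i, ] == a1[j, ], 1) + pmin(a2[i, ] == a2[j, ], 1)
      # allele-pair sharing: count matching alleles allowing one swap
      swap <- pmin(a1[i, ] == a2[j, ], 1) + pmin(a2[i, ] == a1[j, ], 1)
      s <- pmax(shared, pmin(swap, 2))
      d[i, j] <- d[j, i] <- mean((2 - s) / 2)
    }
  }
  xy <- cmdscale(as.dist(d), k = k)
  out <- as_tibble(xy, .name_repair = ~ paste0("mds", seq_len(k))) |>
    mutate(sample = rownames(m), .before = 1)
  if (!is.null(samples)) out <- left_join(out, samples, by = "sample")
  out
}

# Weir-Cockerham (1984) variance components for one biallelic locus.
# freqs/hets/sizes are per-population allele frequency, observed
# heterozygote proportion and sample size. Returns c(a, b, c).
.wc_components <- function(p_i, h_i, n_i) {
  ok <- n_i > 0
  p_i <- p_i[ok]; h_i <- h_i[ok]; n_i <- n_i[ok]
  r <- length(n_i)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST on bi-allelic deletion CNVRs
#'
#' Restricts to deletion-only CNVRs whose copy states are all in {0, 1, 2},
#' where the deletion-allele dosage per sample is unambiguous
#' (`2 - copy`). Computes the Weir-Cockerham per-locus estimator over all
#' populations and the ratio-of-sums global value; pairwise population
#' values use the same estimator on each pair. Negative estimates are
#' retained, not truncated; monomorphic loci are undefined (NA) and excluded
#' from the global sums.
#'
#' @param cnvrs A [cnvr_set()].
#' @param samples Roster tibble (`sample`, `population`).
#' @return Object of class `cnv_fst`: `per_locus` tibble (`cnvr_id`, `fst`,
#'   variance components), `global`, `pairwise` matrix, `n_loci`.
#' @export
fst_deletions <- function(cnvrs, samples) {
  pops <- sort(unique(samples$population))
  if (length(pops) < 2) abort("F_ST needs at least 2 populations")
  regions <- filter(cnvrs$regions, .data$class == "deletion_only")
  # biallelic: every observed copy state in {0,1,2}
  ok_ids <- cnvrs$copies |>
    filter(.data$cnvr_id %in% regions$cnvr_id) |>
    group_by(.data$cnvr_id) |>
    summarise(biallelic = all(.data$copy_number %in% 0:2), .groups = "drop") |>
    filter(.data$biallelic) |>
    pull("cnvr_id")
  if (length(ok_ids) == 0) abort("no bi-allelic deletion loci available")
  m <- copy_matrix(
    cnvr_set(filter(cnvrs$regions, .data$cnvr_id %in% ok_ids),
             filter(cnvrs$copies, .data$cnvr_id %in% ok_ids),
             cnvrs$n_samples),
    samples = samples$sample)
  pop_of <- samples$population[match(rownames(m), samples$sample)]
  locus_stats <- function(pop_subset) {
    sub <- m[pop_of %in% pop_subset, , drop = FALSE]
    po <- pop_of[pop_of %in% pop_subset]
    comps <- vapply(seq_len(ncol(sub)), function(j) {
      dos <- 2 - sub[, j] # deletion-allele dosage 0/1/2
      p_i <- tapply(dos, po, function(z) mean(z) / 2)
      h_i <- tapply(dos, po, function(z) mean(z == 1))
      n_i <- tapply(dos, po, length)
      .wc_components(as.numeric(p_i), as.numeric(h_i), as.numeric(n_i))
    }, numeric(3))
    denom <- colSums(comps)
    fst <- ifelse(abs(denom) < 1e-300, NA_real_, comps[1, ] / denom)
    list(a = comps[1, ], b = comps[2, ], c = comps[3, ], fst = fst)
  }
  all_stats <- locus_stats(pops)
  defined <- !is.na(all_stats$fst)
  global <- sum(all_stats$a[defined]) /
    sum((all_stats$a + all_stats$b + all_stats$c)[defined])
  pw <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (j <= i) next
      st <- locus_stats(pops[c(i, j)])
      def <- !is.na(st$fst)
      pw[i, j] <- pw[j, i] <- sum(st$a[def]) /
        sum((st$a + st$b + st$c)[def])
    }
  }
  structure(list(
    per_locus = tibble(cnvr_id = colnames(m), fst = unname(all_stats$fst),
                       a = unname(all_stats$a), b = unname(all_stats$b),
                       c = unname(all_stats$c)),
    global = global, pairwise = pw, n_loci = ncol(m)),
    class = "cnv_fst")
}

#' @export
print.cnv_fst <- function(x, ...) {
  cat("<cnv_fst> ", x$n_loci, " bi-allelic deletion loci; global F_ST = ",
      format(x$global, digits = 4), "\n", sep = "")
  print(round(x$pairwise, 4))
  invisible(x)
}

#' @export
#' @method tidy cnv_fst
tidy.cnv_fst <- function(x, ...) x$per_locus

#' @export
#' @method glance cnv_fst
glance.cnv_fst <- function(x, ...) {
  tibble(global_fst = x$global, n_loci = x$n_loci,
         mean_fst = mean(x$per_locus$fst, na.rm = TRUE),
         sd_fst = sd(x$per_locus$fst, na.rm = TRUE))
}

#' Flag CNVRs with outlying F_ST
#'
#' Loci whose per-locus F_ST exceeds `mean + k * SD` of the defined
#' per-locus distribution.
#'
#' @param fst A `cnv_fst` object or numeric vector of per-locus values.
#' @param k SD multiplier (default 3; `k = 0` flags everything above the
#'   mean).
#' @return Tibble: `cnvr_id` (or index), `fst`, `z`, `high_fst`.
#' @export
high_fst_cnvrs <- function(fst, k = 3) {
  if (inherits(fst, "cnv_fst")) {
    ids <- fst$per_locus$cnvr_id
    v <- fst$per_locus$fst
  } else {
    ids <- as.character(seq_along(fst))
    v <- as.numeric(fst)
  }
  def <- !is.na(v)
  if (sum(def) < 10) abort("need at least 10 defined per-locus F_ST values")
  mu <- mean(v[def]); s <- sd(v[def])
  z <- (v - mu) / ifelse(s == 0, Inf, s)
  tibble(cnvr_id = ids, fst = v, z = z,
         high_fst = !is.na(v) & v > mu + k * s)
}
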