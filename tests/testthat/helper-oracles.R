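# Brute-force oracles and fixture builders shared across the suite.
# Oracles work per base pair on small layouts and stay independent of the
# interval code they check.

# mark every base covered by a set of half-open intervals on one chromosome
brute_mask <- function(x, chrom, len) {
  mask <- logical(len)
  sub <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$end[i] > sub$start[i]) {
      mask[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
  }
  mask
}

# per-base connected components = union intervals. Components join only on
# a shared base (>= 1 bp), so the scan runs on a doubled grid where
# book-ended intervals leave a one-unit gap instead of touching.
brute_merge <- function(x, layout) {
  out <- list()
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]
    sub <- x[x$chrom == ch, , drop = FALSE]
    mask <- logical(2 * layout$length[ci])
    for (i in seq_len(nrow(sub))) {
      mask[(2 * sub$start[i] + 1):(2 * sub$end[i] - 1)] <- TRUE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch,
                                  start = (starts[keep] - 1) / 2,
                                  end = (ends[keep] + 1) / 2)
    }
  }
  dplyr::bind_rows(out)
}

# does each interval in a overlap >= 1 base of b (per-base scan)?
brute_overlaps_any <- function(a, b, layout) {
  sapply(seq_len(nrow(a)), function(i) {
    ci <- match(a$chrom[i], layout$chrom)
    mask <- brute_mask(b, a$chrom[i], layout$length[ci])
    any(mask[(a$start[i] + 1):a$end[i]])
  })
}

# random interval set on a layout
random_intervals <- function(n, layout, max_len = 50) {
  ci <- sample.int(nrow(layout), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (layout$length[ci] - len))
  tibble::tibble(chrom = layout$chrom[ci], start = start, end = start + len)
}

# phased_snps from an alleles matrix (snps x chromosomes)
make_phased <- function(haps, chrom = "chr1", spacing = 100,
                        samples = NULL) {
  n_samp <- ncol(haps) / 2
  samples <- samples %||% sprintf("S%02d", seq_len(n_samp))
  sites <- tibble::tibble(chrom = chrom,
                          pos = spacing * seq_len(nrow(haps)),
                          ref = "A", alt = "G")
  phased_snps(sites, haps, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small two-chromosome toy layout used by several files
toy_layout <- function(len = 1e5) {
  genome_layout(c("chr1", "chr2"), c(len, len))
}
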