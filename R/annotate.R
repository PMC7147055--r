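# Annotation of consensus CNVRs: novelty against a known-region database,
# carrier frequencies, sharing between population groups in fixed bins,
# per-chromosome density, windowed count correlations, and generic feature
# intersection.

#' Flag CNVRs absent from a known-region database
#'
#' A CNVR is novel iff it overlaps no known region by even 1 bp. This is the
#' conservative reading of novelty: any overlap with a catalogued region
#' disqualifies.
#'
#' @param cnvrs CNVR tibble (or [cnvr_set()]; regions are used).
#' @param known Known-region interval tibble (e.g. a DGV-like BED).
#' @return The region tibble with a logical `novel` column appended.
#' @export
flag_novel <- function(cnvrs, known) {
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else cnvrs
  mutate(regions, novel = !overlaps_any(regions, known))
}

#' Carrier frequency as a percentage
#'
#' @param carrier_count Carrier count(s) (may be a non-integer mean count).
#' @param denominator Cohort size (> 0).
#' @param digits Rounding for the reported percentage (default 0: nearest
#'   whole percent, the convention used in summaries).
#' @return Percentage(s).
#' @examples
#' carrier_frequency(27.1, 232) # 12
#' @export
carrier_frequency <- function(carrier_count, denominator, digits = 0) {
  if (any(denominator <= 0)) abort("frequency denominator must be > 0")
  round(100 * carrier_count / denominator, digits)
}

#' Population-group sharing of CNVRs in fixed genomic bins
#'
#' Tiles the genome in fixed-origin bins (default 5 kb) and marks a group as
#' occupying a bin iff any of its CNVRs overlaps the bin by at least 1 bp.
#' Venn counts are reported over every non-empty group combination.
#'
#' @param cnvrs Interval tibble with a `group` column (one row per CNVR per
#'   group that carries it).
#' @param layout Genome layout.
#' @param bin Bin width in bp (default 5000).
#' @return Object of class `sharing_matrix`: `bins` (occupied bins with one
#'   logical column per group) and `venn` (combination counts).
#' @export
population_sharing <- function(cnvrs, layout, bin = 5000) {
  if (!"group" %in% names(cnvrs)) abort("cnvrs needs a 'group' column")
  groups <- sort(unique(cnvrs$group))
  if (length(groups) == 0) abort("no groups present")
  bins <- genome_bins(layout, bin)
  occ <- matrix(FALSE, nrow(bins), length(groups),
                dimnames = list(NULL, groups))
  for (g in groups) {
    occ[, g] <- overlaps_any(bins, filter(cnvrs, .data$group == g))
  }
  keep <- rowSums(occ) > 0
  bins_occ <- dplyr::bind_cols(bins[keep, ],
                               as_tibble(occ[keep, , drop = FALSE]))
  combo <- apply(occ[keep, , drop = FALSE], 1, function(z) {
    paste(groups[z], collapse = "+")
  })
  venn <- tibble(combination = combo) |>
    count(.data$combination, name = "n_bins") |>
    arrange(dplyr::desc(.data$n_bins))
  structure(list(bins = bins_occ, venn = venn, groups = groups,
                 bin = bin),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("<sharing_matrix> ", nrow(x$bins), " occupied ", x$bin, " bp bins, ",
      length(x$groups), " groups\n", sep = "")
  print(x$venn)
  invisible(x)
}

#' @export
#' @method tidy sharing_matrix
tidy.sharing_matrix <- function(x, ...) x$venn

#' CNVR and CNV density per chromosome
#'
#' Counts per chromosome divided by chromosome length in Mb. When a second
#' density table is supplied, the squared Pearson correlation between the
#' two density vectors is attached for cross-dataset comparison.
#'
#' @param cnvrs CNVR tibble or [cnvr_set()].
#' @param calls Per-sample calls tibble (for CNV-level density); optional.
#' @param layout Genome layout.
#' @param other Optional second density table from this function; adds an
#'   `r_squared` attribute comparing `cnvr_per_mb` vectors.
#' @return Tibble per chromosome: `n_cnvr`, `cnvr_per_mb` and, with `calls`,
#'   `n_cnv`, `cnv_per_mb`.
#' @export
density_by_chromosome <- function(cnvrs, calls = NULL, layout, other = NULL) {
  if (any(layout$length <= 0)) abort("zero-length chromosome in layout")
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else cnvrs
  out <- layout |>
    left_join(count(regions, .data$chrom, name = "n_cnvr"), by = "chrom") |>
    mutate(n_cnvr = tidyr::replace_na(.data$n_cnvr, 0L),
           cnvr_per_mb = .data$n_cnvr / (.data$length / 1e6))
  if (!is.null(calls)) {
    out <- out |>
      left_join(count(calls, .data$chrom, name = "n_cnv"), by = "chrom") |>
      mutate(n_cnv = tidyr::replace_na(.data$n_cnv, 0L),
             cnv_per_mb = .data$n_cnv / (.data$length / 1e6))
  }
  if (!is.null(other)) {
    m <- inner_join(out, other, by = "chrom", suffix = c("", "_other"))
    attr(out, "r_squared") <- cor(m$cnvr_per_mb, m$cnvr_per_mb_other)^2
  }
  out
}

#' Between-population correlation of windowed CNV counts
#'
#' Counts calls per fixed genomic window (default 10 Mb) for each population
#' and returns the population-by-population Pearson correlation matrix of
#' the count vectors. A population with a constant count vector has no
#' defined correlation; those entries are NA, not zero.
#'
#' @param calls Calls tibble with a `population` column.
#' @param layout Genome layout.
#' @param window Window width in bp (default 1e7).
#' @return Symmetric correlation matrix (unit diagonal) with population
#'   dimnames; window counts in attribute `"counts"`.
#' @export
window_correlation <- function(calls, layout, window = 1e7) {
  if (!"population" %in% names(calls)) {
    abort("calls needs a 'population' column")
  }
  pops <- sort(unique(calls$population))
  if (length(pops) < 2) abort("need at least 2 populations")
  bins <- genome_bins(layout, window)
  counts <- matrix(0, nrow(bins), length(pops), dimnames = list(bins$bin_id, pops))
  for (p in pops) {
    sub <- filter(calls, .data$population == p)
    pr <- overlap_pairs(bins, sub)
    tb <- table(factor(pr$a_row, levels = seq_len(nrow(bins))))
    counts[, p] <- as.numeric(tb)
  }
  r <- suppressWarnings(cor(counts))
  diag(r) <- 1
  attr(r, "counts") <- as_tibble(counts) |>
    mutate(bin_id = bins$bin_id, .before = 1)
  r
}

#' Annotate CNVRs with overlapping features
#'
#' Lists every feature (gene, regulatory element, ...) that overlaps each
#' CNVR by at least 1 bp; book-ended features (0 bp shared) are excluded by
#' the half-open convention.
#'
#' @param cnvrs CNVR tibble or [cnvr_set()].
#' @param features Interval tibble with a `name` column.
#' @return Tibble: one row per (CNVR, feature) overlap.
#' @export
intersect_features <- function(cnvrs, features) {
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else cnvrs
  if (!"name" %in% names(features)) abort("features needs a 'name' column")
  pr <- overlap_pairs(regions, features)
  tibble(cnvr_id = regions$cnvr_id[pr$a_row],
         chrom = regions$chrom[pr$a_row],
         start = regions$start[pr$a_row],
         end = regions$end[pr$a_row],
         feature = features$name[pr$b_row],
         feature_start = features$start[pr$b_row],
         feature_end = features$end[pr$b_row])
}

#' Observed-to-expected ratio of feature type counts
#'
#' For each feature type, the expected count is the observed total allocated
#' proportionally to the background composition:
#' `expected_t = total_observed * background_t / total_background`. Types
#' absent from the background are flagged and get no ratio.
#'
#' @param observed Tibble: `type`, `count` (observed in the query set).
#' @param background Tibble: `type`, `count` (genome-wide composition).
#' @return Tibble: `type`, `observed`, `background`, `expected`, `ratio`,
#'   `in_background`.
#' @export
gene_type_ratio <- function(observed, background) {
  tot_obs <- sum(observed$count)
  tot_bg <- sum(background$count)
  if (tot_bg <= 0) abort("background counts must be positive")
  observed |>
    rename(observed = "count") |>
    left_join(rename(background, background = "count"), by = "type") |>
    mutate(in_background = !is.na(.data$background) & .data$background > 0,
           expected = ifelse(.data$in_background,
                             tot_obs * .data$background / tot_bg, NA_real_),
           ratio = .data$observed / .data$expected)
}
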