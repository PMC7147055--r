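# Selection-signature enrichment: are SNPs with high selection scores
# (-log10 p of |iHS|) over-represented inside CNVRs (+/- flanks), do CNV
# states differ between selected and unselected CNVRs, and is the
# tagged x selected joint count larger than independence predicts?

#' Extend CNVRs by symmetric flanks
#'
#' Each region grows by `flank` bp on both sides (clipped to the
#' chromosome). Overlapping flanked regions are *not* merged: SNP membership
#' is tested against the union, so double cover does not double count.
#'
#' @param cnvrs CNVR tibble or [cnvr_set()].
#' @param layout Genome layout.
#' @param flank Flank width in bp (default 5000).
#' @return Interval tibble with the original `cnvr_id` kept if present.
#' @export
flank_regions <- function(cnvrs, layout, flank = 5000) {
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else cnvrs
  lens <- setNames(layout$length, layout$chrom)
  regions |>
    mutate(start = pmax(0, .data$start - flank),
           end = pmin(unname(lens[.data$chrom]), .data$end + flank)) |>
    select(dplyr::any_of(c("cnvr_id", "chrom", "start", "end")))
}

#' Cross-tabulate SNPs by region membership and selection score
#'
#' Each SNP is counted exactly once into a 2x2 table: inside/outside the
#' flanked regions (>= 1 bp membership, i.e. the 1-based position p is in a
#' region `[s, e)` iff `s < p <= e`) by score above/at-or-below the
#' threshold.
#'
#' @param scores Score tibble (`chrom`, `pos`, `score`; `pos0` added by
#'   [read_scores()] or derived here).
#' @param regions Flanked region tibble.
#' @param threshold Score threshold (default 3.0, i.e. p < 1e-3).
#' @return 2x2 matrix with dimnames
#'   `c("in_region", "out_region") x c("significant", "not_significant")`.
#' @export
snp_region_table <- function(scores, regions, threshold = 3.0) {
  if (!"pos0" %in% names(scores)) scores <- mutate(scores, pos0 = .data$pos - 1)
  pts <- tibble(chrom = scores$chrom, start = scores$pos0,
                end = scores$pos0 + 1)
  inside <- overlaps_any(pts, regions)
  sig <- scores$score > threshold
  matrix(c(sum(inside & sig), sum(!inside & sig),
           sum(inside & !sig), sum(!inside & !sig)),
         nrow = 2,
         dimnames = list(c("in_region", "out_region"),
                         c("significant", "not_significant")))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction;
#' `df = (r - 1) * (k - 1)`; p from the chi-square distribution. Expected
#' counts must all be positive.
#'
#' @param table Non-negative count matrix, at least 2x2.
#' @return Object of class `cnv_enrichment`: `table`, `expected`,
#'   `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) abort("table must be at least 2x2")
  if (any(table < 0)) abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(table = table, expected = ct$expected,
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value),
            class = "cnv_enrichment")
}

#' @export
print.cnv_enrichment <- function(x, ...) {
  cat("<cnv_enrichment> chi-square = ", format(x$statistic, digits = 6),
      ", df = ", x$df, ", p = ", format(x$p_value, digits = 3), "\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' @export
#' @method tidy cnv_enrichment
tidy.cnv_enrichment <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table))) |>
    setNames(c("row", "column", "count"))
}

#' @export
#' @method glance cnv_enrichment
glance.cnv_enrichment <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' CNV states cross-tabulated by CNVR selection status
#'
#' Every (CNVR, sample) pair contributes one count: deletion (copy < 2),
#' wild type (copy = 2, including samples with no call, which sit at the
#' diploid reference by convention) or insertion (copy > 2). Rows split
#' CNVRs by whether they contain at least one SNP above the selection
#' threshold. Mean CNV frequency per row is
#' `(deletions + insertions) / row total`, as a percentage.
#'
#' @param cnvrs A [cnvr_set()].
#' @param selected Logical vector along `cnvrs$regions` (or tibble with
#'   `cnvr_id`, `selected`).
#' @return List: `table` (2x3 matrix), `row_summary` (tibble with mean CNV
#'   frequency per row), `test` (the [chi_square()] result).
#' @export
cnv_state_by_selection <- function(cnvrs, selected) {
  regions <- cnvrs$regions
  if (is.data.frame(selected)) {
    selected <- selected$selected[match(regions$cnvr_id, selected$cnvr_id)]
  }
  stopifnot(length(selected) == nrow(regions))
  n <- cnvrs$n_samples
  states <- cnvrs$copies |>
    mutate(state = dplyr::case_when(.data$copy_number < 2 ~ "deletion",
                                    .data$copy_number > 2 ~ "insertion",
                                    TRUE ~ "wild_type"))
  sel_of <- setNames(selected, regions$cnvr_id)
  counted <- states |>
    mutate(selected = sel_of[.data$cnvr_id]) |>
    count(.data$selected, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0)
  for (col in c("deletion", "wild_type", "insertion")) {
    if (!col %in% names(counted)) counted[[col]] <- 0
  }
  # samples without a call are wild type: total pairs = n_cnvr_row * n
  row_of <- function(sel) {
    sub <- counted[counted$selected == sel, ]
    del <- sum(sub$deletion); ins <- sum(sub$insertion)
    wt_called <- sum(sub$wild_type)
    total <- sum(selected == sel) * n
    c(deletion = del, wild_type = total - del - ins, insertion = ins)
  }
  tab <- rbind(selected = row_of(TRUE), unselected = row_of(FALSE))
  colnames(tab) <- c("deletions", "wild_type", "insertions")
  row_summary <- tibble(
    row = rownames(tab),
    n_cnvr = c(sum(selected), sum(!selected)),
    mean_cnv_frequency_pct =
      unname(100 * (tab[, "deletions"] + tab[, "insertions"]) /
               rowSums(tab))
  )
  testable <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  list(table = tab, row_summary = row_summary,
       test = if (testable) chi_square(tab) else NULL)
}

#' Expected CNVR count under tagged/selected independence
#'
#' If tagging and selection were independent, the expected number of CNVRs
#' with both properties is `n_tagged * n_selected / n_total`.
#'
#' @param n_tagged,n_selected Marginal CNVR counts.
#' @param n_total Total CNVR count (> 0).
#' @return List: `expected` (raw) and `expected_rounded`.
#' @examples
#' joint_expected(2693, 372, 7608) # 131.68 -> 132
#' @export
joint_expected <- function(n_tagged, n_selected, n_total) {
  if (n_total <= 0) abort("n_total must be positive")
  if (n_tagged > n_total || n_selected > n_total) {
    abort("marginal counts cannot exceed the total")
  }
  e <- n_tagged * n_selected / n_total
  list(expected = e, expected_rounded = round(e))
}

#' Test the excess of jointly tagged and selected CNVRs
#'
#' Builds the 2x2 cross-classification of CNVRs (tagged x selected) from the
#' margins and the observed joint count, and tests independence with a
#' Pearson chi-square (default) or Fisher's exact test.
#'
#' @param observed_both CNVRs with both properties.
#' @param n_tagged,n_selected Marginal counts.
#' @param n_total Total CNVR count.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return Tibble: `observed`, `expected`, `statistic` (NA for Fisher),
#'   `p_value`, `method`.
#' @export
joint_excess_test <- function(observed_both, n_tagged, n_selected, n_total,
                              method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (observed_both > min(n_tagged, n_selected)) {
    abort("observed joint count exceeds a margin")
  }
  tab <- matrix(c(observed_both, n_tagged - observed_both,
                  n_selected - observed_both,
                  n_total - n_tagged - n_selected + observed_both),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("tagged", "untagged"),
                                c("selected", "unselected")))
  if (any(tab < 0)) abort("inconsistent margins: negative cell implied")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate margins")
  }
  exp_both <- joint_expected(n_tagged, n_selected, n_total)$expected
  if (method == "chisq") {
    r <- chi_square(tab)
    tibble(observed = observed_both, expected = exp_both,
           statistic = r$statistic, p_value = r$p_value, method = "chisq")
  } else {
    f <- stats::fisher.test(tab)
    tibble(observed = observed_both, expected = exp_both,
           statistic = NA_real_, p_value = f$p.value, method = "fisher")
  }
}

#' Flag CNVRs containing selection-scored SNPs
#'
#' A CNVR is "selected" iff at least one SNP with score above the threshold
#' falls inside its flanked interval.
#'
#' @param cnvrs A [cnvr_set()] or region tibble.
#' @param scores Score tibble.
#' @param layout Genome layout.
#' @param flank Flank width (default 5000, consistent with the SNP
#'   membership table).
#' @param threshold Score threshold (default 3.0).
#' @return Tibble: `cnvr_id`, `selected`.
#' @export
flag_selected <- function(cnvrs, scores, layout, flank = 5000,
                          threshold = 3.0) {
  regions <- if (inherits(cnvrs, "cnvr_set")) cnvrs$regions else cnvrs
  flanked <- flank_regions(regions, layout, flank)
  if (!"pos0" %in% names(scores)) scores <- mutate(scores, pos0 = .data$pos - 1)
  hi <- filter(scores, .data$score > threshold)
  pts <- tibble(chrom = hi$chrom, start = hi$pos0, end = hi$pos0 + 1)
  hit <- overlaps_any(flanked, pts)
  tibble(cnvr_id = regions$cnvr_id, selected = hit)
}
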