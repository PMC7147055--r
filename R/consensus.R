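# From per-sample CNV calls to high-confidence consensus CNVRs. A CNVR is a
# maximal union of overlapping (>= 1 bp) call intervals across samples; the
# fixed pipeline order is merge -> outlier-sample removal -> re-merge ->
# singleton filter -> consensus intersection of the two caller sets.

#' Classify a CNV region from its non-reference copy states
#'
#' @param copies Integer copy numbers of the region's carriers (reference
#'   diploid = 2; copy-2 entries are ignored).
#' @return `"deletion_only"`, `"insertion_only"` or `"mixed"`.
#' @export
classify_region <- function(copies) {
  nonref <- copies[copies != 2]
  if (length(nonref) == 0) {
    abort("all-reference region: nothing to classify (should not survive merge)")
  }
  if (all(nonref < 2)) return("deletion_only")
  if (all(nonref > 2)) return("insertion_only")
  "mixed"
}

#' Construct a CNVR set
#'
#' Container pairing region-level rows with the per-sample copy states that
#' support them. Samples without an entry in `copies` at a region are at the
#' diploid reference (copy 2) by convention, not missing.
#'
#' @param regions Tibble: `cnvr_id`, `chrom`, `start`, `end`, `length`,
#'   `class`, `carrier_count`, `n_calls`, `frequency`.
#' @param copies Tibble: `cnvr_id`, `sample`, `copy_number`,
#'   `fractional_copy`.
#' @param n_samples Cohort denominator used for `frequency`.
#' @return Object of class `cnvr_set`.
#' @export
cnvr_set <- function(regions, copies, n_samples) {
  structure(list(regions = as_tibble(regions), copies = as_tibble(copies),
                 n_samples = n_samples),
            class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat("<cnvr_set> ", nrow(x$regions), " CNVRs, ", nrow(x$copies),
      " CNV calls over ", x$n_samples, " samples\n", sep = "")
  if (nrow(x$regions) > 0) print(utils::head(x$regions, 5))
  invisible(x)
}

#' @export
#' @method tidy cnvr_set
tidy.cnvr_set <- function(x, ...) x$regions

#' @export
#' @method glance cnvr_set
glance.cnvr_set <- function(x, ...) region_summary(x)

#' Merge one caller's CNV calls into CNV regions
#'
#' CNVRs are the maximal unions of call intervals that overlap by at least
#' 1 bp across samples. A sample with several overlapping calls inside one
#' CNVR contributes the copy number of its longest call. Calls asserting the
#' diploid reference (copy 2) carry no CNV claim and are dropped on entry.
#'
#' @param calls Calls tibble (`chrom`, `start`, `end`, `sample`,
#'   `copy_number`, optionally `fractional_copy`).
#' @param n_samples Frequency denominator; defaults to the number of
#'   distinct samples seen in `calls`.
#' @param id_prefix Prefix for generated CNVR ids.
#' @return A [cnvr_set()].
#' @export
merge_calls_to_cnvr <- function(calls, n_samples = dplyr::n_distinct(calls$sample),
                                id_prefix = "cnvr") {
  if (nrow(calls) == 0) {
    return(cnvr_set(
      tibble(cnvr_id = character(), chrom = character(), start = numeric(),
             end = numeric(), length = numeric(), class = character(),
             carrier_count = integer(), n_calls = integer(),
             frequency = numeric()),
      tibble(cnvr_id = character(), sample = character(),
             copy_number = numeric(), fractional_copy = numeric()),
      n_samples))
  }
  validate_intervals(calls, what = "CNV call")
  if (!"fractional_copy" %in% names(calls)) {
    calls$fractional_copy <- as.numeric(calls$copy_number)
  }
  calls <- filter(calls, .data$copy_number != 2)
  regions <- merge_intervals(calls)
  regions$cnvr_id <- sprintf("%s_%05d", id_prefix, seq_len(nrow(regions)))
  pairs <- overlap_pairs(regions, calls)
  assigned <- calls[pairs$b_row, ] |>
    mutate(cnvr_id = regions$cnvr_id[pairs$a_row],
           call_len = .data$end - .data$start)
  copies <- assigned |>
    group_by(.data$cnvr_id, .data$sample) |>
    arrange(dplyr::desc(.data$call_len)) |>
    summarise(copy_number = first(.data$copy_number),
              fractional_copy = first(.data$fractional_copy),
              .groups = "drop")
  stats <- assigned |>
    group_by(.data$cnvr_id) |>
    summarise(n_calls = n(), .groups = "drop")
  cls <- copies |>
    group_by(.data$cnvr_id) |>
    summarise(class = classify_region(.data$copy_number),
              carrier_count = sum(.data$copy_number != 2), .groups = "drop")
  regions <- regions |>
    left_join(stats, by = "cnvr_id") |>
    left_join(cls, by = "cnvr_id") |>
    mutate(length = .data$end - .data$start,
           frequency = .data$carrier_count / n_samples) |>
    select("cnvr_id", "chrom", "start", "end", "length", "class",
           "carrier_count", "n_calls", "frequency")
  cnvr_set(regions, copies, n_samples)
}

#' Flag samples with exceptionally many CNV calls
#'
#' Samples whose total call count exceeds `median + k * MAD` of the cohort
#' are flagged as outliers. The report carries group means and a Welch
#' two-sample t-test of flagged versus retained counts; MDS coordinates of
#' the per-sample call-presence profile are returned for plotting parity
#' with the visual outlier screens common in this kind of QC.
#'
#' @param calls Calls tibble (any caller or several combined).
#' @param samples Optional sample roster; samples without calls count 0.
#' @param k MAD multiplier (default 5).
#' @return Object of class `outlier_report`: `outliers` (ids), `counts`
#'   (per-sample tibble), `test` (group means and p-value), `mds`
#'   (2-d coordinates).
#' @export
detect_outlier_samples <- function(calls, samples = NULL, k = 5) {
  ids <- if (!is.null(samples)) samples$sample else unique(calls$sample)
  if (length(ids) < 10) {
    abort("outlier detection needs at least 10 samples (threshold unstable)")
  }
  counts <- calls |>
    count(.data$sample, name = "n_calls") |>
    dplyr::right_join(tibble(sample = ids), by = "sample") |>
    mutate(n_calls = tidyr::replace_na(.data$n_calls, 0L))
  thr <- median(counts$n_calls) + k * mad(counts$n_calls)
  counts <- mutate(counts, outlier = .data$n_calls > thr)
  flagged <- counts$sample[counts$outlier]
  pval <- if (sum(counts$outlier) >= 2 && sum(!counts$outlier) >= 2) {
    t.test(counts$n_calls[counts$outlier],
           counts$n_calls[!counts$outlier])$p.value
  } else NA_real_
  test <- tibble(
    mean_outliers = mean(counts$n_calls[counts$outlier]),
    mean_retained = mean(counts$n_calls[!counts$outlier]),
    threshold = thr, k = k, p_welch = pval
  )
  mds <- .call_profile_mds(calls, ids)
  structure(list(outliers = flagged, counts = counts, test = test, mds = mds),
            class = "outlier_report")
}

# MDS of per-sample region-presence profiles (manhattan distance); the
# count-based rule does the flagging, these coordinates are for plots.
.call_profile_mds <- function(calls, ids) {
  if (nrow(calls) == 0) {
    return(tibble(sample = ids, mds1 = 0, mds2 = 0))
  }
  regions <- merge_intervals(calls)
  regions$row <- seq_len(nrow(regions))
  pairs <- overlap_pairs(regions, calls)
  m <- matrix(0L, nrow = length(ids), ncol = nrow(regions),
              dimnames = list(ids, NULL))
  samp <- calls$sample[pairs$b_row]
  keep <- samp %in% ids
  m[cbind(match(samp[keep], ids), pairs$a_row[keep])] <- 1L
  d <- dist(m, method = "manhattan")
  k <- min(2, length(ids) - 1)
  xy <- cmdscale(d, k = k)
  tibble(sample = ids, mds1 = xy[, 1],
         mds2 = if (k > 1) xy[, 2] else 0)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", length(x$outliers), " of ", nrow(x$counts),
      " samples flagged\n", sep = "")
  print(x$test)
  invisible(x)
}

#' @export
#' @method tidy outlier_report
tidy.outlier_report <- function(x, ...) x$counts

#' @export
#' @method glance outlier_report
glance.outlier_report <- function(x, ...) x$test

#' Remove CNVRs carried by fewer than two samples
#'
#' @param x A [cnvr_set()].
#' @param min_carriers Minimum carrier count to retain (default 2).
#' @return Filtered `cnvr_set`.
#' @export
filter_singletons <- function(x, min_carriers = 2) {
  keep <- x$regions$cnvr_id[x$regions$carrier_count >= min_carriers]
  cnvr_set(filter(x$regions, .data$cnvr_id %in% keep),
           filter(x$copies, .data$cnvr_id %in% keep),
           x$n_samples)
}

#' Consensus intersection of two caller CNVR sets
#'
#' Retains the A-side regions (boundaries from caller A) that overlap any
#' B-side region by at least 1 bp. Under the half-open convention, regions
#' that merely touch (`endA == startB`) share 0 bp and are dropped.
#'
#' @param a A [cnvr_set()] (the fine-grained caller).
#' @param b A `cnvr_set` or plain interval tibble (the coarse caller).
#' @return The filtered A-side `cnvr_set`.
#' @export
consensus_intersect <- function(a, b) {
  b_regions <- if (inherits(b, "cnvr_set")) b$regions else b
  hit <- overlaps_any(a$regions, b_regions)
  keep <- a$regions$cnvr_id[hit]
  cnvr_set(filter(a$regions, .data$cnvr_id %in% keep),
           filter(a$copies, .data$cnvr_id %in% keep),
           a$n_samples)
}

#' Descriptive summary of a CNVR set
#'
#' One-row tibble in the shape of a caller-comparison table: CNVR count,
#' total CNV count, mean CNV per CNVR, mean CNVR per individual (total CNV
#' divided by sample count), length statistics (kb / Mb) and per-class
#' counts.
#'
#' @param x A [cnvr_set()].
#' @param n_samples Denominator for the per-individual mean; defaults to the
#'   set's stored cohort size.
#' @return One-row tibble.
#' @export
region_summary <- function(x, n_samples = x$n_samples) {
  r <- x$regions
  if (nrow(r) == 0) abort("empty CNVR set has no summary")
  total_cnv <- nrow(x$copies)
  tibble(
    n_cnvr = nrow(r),
    total_cnv = total_cnv,
    mean_cnv_per_cnvr = total_cnv / nrow(r),
    mean_cnvr_per_individual = total_cnv / n_samples,
    mean_length_kb = mean(r$length) / 1e3,
    sd_length_kb = sd(r$length) / 1e3,
    median_length_kb = median(r$length) / 1e3,
    total_length_mb = sum(r$length) / 1e6,
    n_deletion_only = sum(r$class == "deletion_only"),
    n_insertion_only = sum(r$class == "insertion_only"),
    n_mixed = sum(r$class == "mixed")
  )
}

#' Run the full two-caller consensus chain
#'
#' Fixed stage order: merge each caller's calls, flag outlier samples on the
#' combined call counts, drop them from both call sets, re-merge, remove
#' singleton CNVRs from both sets, then retain the A-side regions confirmed
#' by at least 1 bp of B-side overlap.
#'
#' @param calls_a Fine-grained caller's calls (defines consensus boundaries).
#' @param calls_b Coarse caller's calls.
#' @param samples Sample roster tibble (`sample`, `population`, `group`).
#' @param outlier_k MAD multiplier passed to [detect_outlier_samples()].
#' @return List of class `consensus_result`: `consensus` (A-side `cnvr_set`),
#'   `cnvrs_a`, `cnvrs_b` (post-filter per-caller sets), `outliers`
#'   (`outlier_report`), `retained_samples`, `log` (stage order).
#' @export
build_consensus <- function(calls_a, calls_b, samples, outlier_k = 5) {
  merged_a0 <- merge_calls_to_cnvr(calls_a, n_samples = nrow(samples),
                                   id_prefix = "a")
  merged_b0 <- merge_calls_to_cnvr(calls_b, n_samples = nrow(samples),
                                   id_prefix = "b")
  outliers <- detect_outlier_samples(bind_rows(calls_a, calls_b),
                                     samples = samples, k = outlier_k)
  retained <- setdiff(samples$sample, outliers$outliers)
  a1 <- filter(calls_a, .data$sample %in% retained)
  b1 <- filter(calls_b, .data$sample %in% retained)
  cnvrs_a <- merge_calls_to_cnvr(a1, n_samples = length(retained),
                                 id_prefix = "a") |> filter_singletons()
  cnvrs_b <- merge_calls_to_cnvr(b1, n_samples = length(retained),
                                 id_prefix = "b") |> filter_singletons()
  consensus <- consensus_intersect(cnvrs_a, cnvrs_b)
  structure(list(
    consensus = consensus, cnvrs_a = cnvrs_a, cnvrs_b = cnvrs_b,
    outliers = outliers, retained_samples = retained,
    log = c("merge_per_caller", "outlier_removal", "re_merge",
            "singleton_filter", "consensus_intersect")
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", nrow(x$consensus$regions),
      " consensus CNVRs (A: ", nrow(x$cnvrs_a$regions), ", B: ",
      nrow(x$cnvrs_b$regions), "); ", length(x$outliers$outliers),
      " outlier samples removed\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy consensus_result
tidy.consensus_result <- function(x, ...) x$consensus$regions

#' @export
#' @method glance consensus_result
glance.consensus_result <- function(x, ...) {
  bind_rows(
    mutate(region_summary(x$cnvrs_a), set = "caller_a", .before = 1),
    mutate(region_summary(x$cnvrs_b), set = "caller_b", .before = 1),
    mutate(region_summary(x$consensus), set = "consensus", .before = 1)
  )
}
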