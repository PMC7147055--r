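#' Define a genome layout
#'
#' A genome layout is the ordered table of chromosome labels and lengths that
#' every interval in the pipeline is validated against. It stands in for a
#' reference-genome index (e.g. the autosomes of a human assembly).
#'
#' @param chrom Character vector of unique chromosome labels.
#' @param length Positive integer vector of chromosome lengths in bp.
#' @return A tibble with columns `chrom` and `length`, ordered as given.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e7, 1e7))
#' @export
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom) > 0) {
    abort("chromosome labels must be unique")
  }
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    abort("chromosome lengths must be positive integers")
  }
  tibble(chrom = as.character(chrom), length = length)
}

#' Validate a table of genomic intervals
#'
#' Checks the 0-based half-open convention (`0 <= start < end`) and, when a
#' layout is supplied, that every chromosome is known and no interval runs off
#' its end. Returns the input invisibly so it can sit inside a pipe.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and any extra columns.
#' @param layout Optional genome layout from [genome_layout()].
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, layout = NULL, what = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(paste0(
      what, " row ", bad[1], " violates 0 <= start < end (start=",
      x$start[bad[1]], ", end=", x$end[bad[1]], ")"
    ))
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(x$chrom), layout$chrom)
    if (length(unknown) > 0) {
      abort(paste0(what, " uses chromosome(s) absent from layout: ",
                   paste(unknown, collapse = ", ")))
    }
    lens <- setNames(layout$length, layout$chrom)
    over <- which(x$end > lens[x$chrom])
    if (length(over) > 0) {
      abort(paste0(what, " row ", over[1], " extends past the end of ",
                   x$chrom[over[1]]))
    }
  }
  invisible(x)
}

# Half-open [start, end) -> IRanges (1-based closed). Integer bp means the
# two conventions agree on every overlap/containment question.
.as_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Merge overlapping intervals into their union
#'
#' Collapses all intervals that overlap by at least 1 bp (per chromosome) into
#' maximal union intervals. Book-ended intervals (`end == start`) do not
#' overlap under the half-open convention and are not merged.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @return Tibble of disjoint union intervals, sorted by chromosome and start.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  x |>
    group_by(.data$chrom) |>
    dplyr::reframe({
      # min.gapwidth = 0: book-ended intervals share no base, never merge
      r <- IRanges::reduce(.as_iranges(dplyr::pick(dplyr::everything())),
                           min.gapwidth = 0L)
      tibble(start = BiocGenerics::start(r) - 1, end = BiocGenerics::end(r))
    }) |>
    arrange(.data$chrom, .data$start) |>
    as_tibble()
}

#' Flag intervals of one set that overlap another set
#'
#' @param a,b Interval tibbles.
#' @return Logical vector along the rows of `a`: `TRUE` where the interval
#'   shares at least 1 bp with any interval in `b`.
#' @export
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    hit <- IRanges::overlapsAny(.as_iranges(a[ia, ]),
                                .as_iranges(b[b$chrom == ch, ]))
    out[ia] <- hit
  }
  out
}

#' Overlap between interval pairs of two sets
#'
#' Every (a, b) pair sharing at least 1 bp, as row indices into the inputs.
#'
#' @param a,b Interval tibbles.
#' @return Tibble with columns `a_row`, `b_row`.
#' @export
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_row = integer(), b_row = integer()))
  }
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(.as_iranges(a[ia, ]), .as_iranges(b[ib, ]))
    res[[ch]] <- tibble(a_row = ia[S4Vectors::queryHits(hits)],
                        b_row = ib[S4Vectors::subjectHits(hits)])
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) tibble(a_row = integer(), b_row = integer()) else
    arrange(out, .data$a_row, .data$b_row)
}

#' Total length of A-intervals that overlap B
#'
#' Sums the *full* length of every interval in `a` that shares at least 1 bp
#' with any interval in `b`. This is deliberately not the intersection length:
#' the statistic of interest is "how much CNV length is found by both
#' methods", i.e. the retained-set total length, so an A-interval counts in
#' full once any part of it is confirmed by B.
#'
#' @param a,b Interval tibbles.
#' @return Total bp (scalar). Empty sets give 0.
#' @export
total_overlap_length <- function(a, b) {
  if (nrow(a) == 0) return(0)
  hit <- overlaps_any(a, b)
  sum((a$end - a$start)[hit])
}

#' Fixed-origin genomic bins
#'
#' Tiles each chromosome with bins of fixed width anchored at 0; the last,
#' possibly partial, bin is kept.
#'
#' @param layout Genome layout.
#' @param bin Bin width in bp (default 5000).
#' @return Interval tibble with an extra `bin_id` column.
#' @export
genome_bins <- function(layout, bin = 5000) {
  stopifnot(bin > 0)
  layout |>
    group_by(.data$chrom) |>
    dplyr::reframe({
      len <- .data$length[1]
      s <- seq(0, len - 1, by = bin)
      tibble(start = s, end = pmin(s + bin, len))
    }) |>
    mutate(bin_id = paste0(.data$chrom, ":", .data$start)) |>
    as_tibble()
}
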