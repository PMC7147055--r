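# Readers and writers for every flat format the pipeline touches: BED3+ for
# intervals and CNV calls, a phased GT-only VCF subset for SNPs, and TSV for
# sample metadata, selection scores and chromosome sizes. All outputs carry a
# one-line "#" header recording tool version and, where relevant, the seed.

.header_comment <- function(seed = NULL) {
  paste0("# cnvrpipe ", as.character(packageVersion("cnvrpipe")),
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

#' Read a BED3+ file
#'
#' Reads tab-separated BED (0-based half-open). The first three columns become
#' `chrom`, `start`, `end`; extra columns are preserved verbatim as `V4`,
#' `V5`, ... unless the file carries its own `#`-prefixed column header.
#'
#' @param path File path.
#' @param layout Optional genome layout; intervals are validated against it.
#' @param col_names Optional names for the extra columns (beyond the first 3).
#' @return Interval tibble.
#' @export
read_bed <- function(path, layout = NULL, col_names = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(paste0("BED parse error at line ", which(nf < 3)[1],
                 ": fewer than 3 tab-separated fields"))
  }
  k <- min(nf)
  mat <- t(vapply(parts, function(p) p[seq_len(k)], character(k)))
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("BED parse error at line ", bad[1],
                 ": non-numeric start/end"))
  }
  out <- tibble(chrom = mat[, 1], start = start, end = end)
  if (k > 3) {
    extra <- as_tibble(mat[, 4:k, drop = FALSE], .name_repair = "minimal")
    names(extra) <- col_names %||% paste0("V", 4:k)
    extra <- utils::type.convert(extra, as.is = TRUE)
    out <- dplyr::bind_cols(out, extra)
  }
  validate_intervals(out, layout, what = "BED")
  out
}

#' Write intervals as BED
#'
#' @param x Interval tibble; columns beyond `chrom`, `start`, `end` are
#'   written as extra BED columns in order.
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, seed = NULL) {
  validate_intervals(x, what = "BED")
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  df <- as.data.frame(x[, c("chrom", "start", "end", extra)])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tibble as commented TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(seed), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a commented TSV
#'
#' @param path File path.
#' @return Tibble (header comment lines skipped).
#' @export
read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `population`, `group`.
#' @return Tibble; errors if sample ids repeat or assignments are missing.
#' @export
read_samples <- function(path) {
  x <- read_tsv_commented(path)
  need <- c("sample", "population", "group")
  if (!all(need %in% names(x))) {
    abort("sample table needs columns: sample, population, group")
  }
  if (anyDuplicated(x$sample) > 0) abort("duplicate sample ids")
  if (anyNA(x[need])) abort("every sample needs a population and a group")
  x
}

#' Read per-SNP selection scores
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `score`
#'   (-log10 p of |iHS|, non-negative).
#' @return Tibble with `pos0` (0-based) added.
#' @export
read_scores <- function(path) {
  x <- read_tsv_commented(path)
  if (!all(c("chrom", "pos", "score") %in% names(x))) {
    abort("score table needs columns: chrom, pos, score")
  }
  if (any(x$score < 0)) abort("selection scores must be non-negative")
  mutate(x, pos0 = .data$pos - 1)
}

#' Read chromosome sizes
#'
#' @param path TSV with columns `chrom`, `length`.
#' @return Genome layout tibble.
#' @export
read_genome <- function(path) {
  x <- read_tsv_commented(path)
  if (!all(c("chrom", "length") %in% names(x))) {
    abort("genome table needs columns: chrom, length")
  }
  genome_layout(x$chrom, x$length)
}

#' Read CNV calls from BED
#'
#' Expects the extra columns `sample`, `copy_number`, `fractional_copy`,
#' `caller` after the three coordinate columns.
#'
#' @param path BED file path.
#' @param layout Optional genome layout for validation.
#' @return Calls tibble.
#' @export
read_calls <- function(path, layout = NULL) {
  x <- read_bed(path, layout,
                col_names = c("sample", "copy_number", "fractional_copy",
                              "caller"))
  if (!all(c("sample", "copy_number") %in% names(x))) {
    abort("call BED needs sample and copy_number columns (4 and 5)")
  }
  if (any(x$copy_number < 0)) abort("copy numbers must be >= 0")
  x
}

#' Write CNV calls as BED
#'
#' @param calls Calls tibble.
#' @param path Output path.
#' @param seed Optional seed for the header comment.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, seed = NULL) {
  write_bed(calls[, c("chrom", "start", "end", "sample", "copy_number",
                      "fractional_copy", "caller")], path, seed = seed)
}
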