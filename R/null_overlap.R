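# Random-placement null for the two-caller overlap: how much caller-A CNVR
# length would land inside caller-B regions if the observed A lengths were
# scattered uniformly over the genome.

#' Place interval lengths uniformly at random on a genome
#'
#' Each length is dropped independently and uniformly over all valid start
#' positions genome-wide: a chromosome is chosen with probability
#' proportional to its number of valid starts (`chrom_length - L + 1`), then
#' a start is drawn uniformly. Placed intervals may overlap each other.
#'
#' @param lengths Integer vector of interval lengths (bp).
#' @param layout Genome layout.
#' @return Interval tibble, one row per input length (input order).
#' @export
place_random <- function(lengths, layout) {
  if (length(lengths) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  too_big <- lengths > max(layout$length)
  if (any(too_big)) {
    abort(paste0("length ", lengths[which(too_big)[1]],
                 " exceeds every chromosome in the layout"))
  }
  n <- length(lengths)
  chrom <- character(n)
  start <- numeric(n)
  for (i in seq_len(n)) {
    L <- lengths[i]
    valid <- pmax(layout$length - L + 1, 0)
    ci <- sample.int(nrow(layout), 1, prob = valid)
    chrom[i] <- layout$chrom[ci]
    # uniform over 0 .. (chrom_length - L); sample.int avoids FP edge cases
    start[i] <- sample.int(valid[ci], 1) - 1
  }
  tibble(chrom = chrom, start = start, end = start + lengths)
}

#' Expected by-chance overlap with a fixed region set
#'
#' Repeats [place_random()] `n_sims` times; in each replicate the overlap is
#' the total full length of placed intervals that share at least 1 bp with
#' `set_b` (see [total_overlap_length()]). Returns the replicate mean and
#' sample SD next to the observed value for the real A set.
#'
#' @param set_a Observed A-side intervals (their lengths are re-placed and
#'   their observed overlap reported for comparison).
#' @param set_b Fixed B-side intervals.
#' @param layout Genome layout.
#' @param n_sims Number of random placements (default 100).
#' @param seed Seed for the placement RNG (required for reproducibility).
#' @return Object of class `overlap_null`: observed bp, simulated mean/SD,
#'   replicate totals, `n_sims`, `seed`.
#' @export
expected_overlap <- function(set_a, set_b, layout, n_sims = 100, seed) {
  stopifnot(n_sims >= 1)
  validate_intervals(set_a, layout, what = "set A")
  if (nrow(set_b) > 0) validate_intervals(set_b, layout, what = "set B")
  lengths <- set_a$end - set_a$start
  observed <- total_overlap_length(set_a, set_b)
  set.seed(seed)
  sims <- vapply(seq_len(n_sims), function(i) {
    total_overlap_length(place_random(lengths, layout), set_b)
  }, numeric(1))
  structure(list(observed_bp = observed, mean_bp = mean(sims),
                 sd_bp = if (n_sims > 1) sd(sims) else 0,
                 replicates = sims, n_sims = n_sims, seed = seed),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat("<overlap_null> observed ", format(x$observed_bp / 1e6, digits = 4),
      " Mb; simulated ", format(x$mean_bp / 1e6, digits = 4), " +/- ",
      format(x$sd_bp / 1e6, digits = 3), " Mb (", x$n_sims, " sims)\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy overlap_null
tidy.overlap_null <- function(x, ...) {
  tibble(replicate = seq_len(x$n_sims), overlap_bp = x$replicates)
}

#' @export
#' @method glance overlap_null
glance.overlap_null <- function(x, ...) {
  tibble(observed_bp = x$observed_bp, mean_bp = x$mean_bp, sd_bp = x$sd_bp,
         n_sims = x$n_sims, seed = x$seed)
}
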