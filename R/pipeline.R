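# End-to-end driver: simulate -> consensus -> null-overlap -> annotate ->
# taghap -> selection -> popstruct. Each stage reads its inputs from the
# output directory and writes flat files there, so partial reruns resume
# from whatever already exists; a JSON manifest records version, seed,
# resolved parameters and output digests.

.stage_order <- c("simulate", "consensus", "null_overlap", "annotate",
                  "taghap", "selection", "popstruct")

.need_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(paste0("missing ", basename(path), "; run stage '", produced_by,
                 "' first"))
  }
  path
}

# consensus stage outputs reassembled into a cnvr_set
.read_consensus <- function(out_dir) {
  regions <- read_tsv_commented(
    .need_file(file.path(out_dir, "consensus", "consensus.tsv"), "consensus"))
  copies <- read_tsv_commented(
    .need_file(file.path(out_dir, "consensus", "copies.tsv"), "consensus"))
  retained <- read_tsv_commented(
    .need_file(file.path(out_dir, "consensus", "retained_samples.tsv"),
               "consensus"))
  cnvr_set(regions, copies, nrow(retained))
}

.read_inputs <- function(out_dir) {
  ind <- file.path(out_dir, "inputs")
  list(
    layout = read_genome(.need_file(file.path(ind, "genome.tsv"), "simulate")),
    samples = read_samples(.need_file(file.path(ind, "samples.tsv"),
                                      "simulate")),
    calls_a = read_calls(.need_file(file.path(ind, "caller_a.bed"),
                                    "simulate")),
    calls_b = read_calls(.need_file(file.path(ind, "caller_b.bed"),
                                    "simulate")),
    known = read_bed(.need_file(file.path(ind, "known.bed"), "simulate")),
    scores = read_scores(.need_file(file.path(ind, "scores.tsv"),
                                    "simulate")),
    snps_path = file.path(ind, "snps.vcf"))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the stages in their fixed order, writing every stage's outputs
#' under `out_dir` and a `manifest.json` recording tool version, seed,
#' resolved parameters and output-file digests. Stages whose outputs
#' already exist are skipped unless `overwrite = TRUE`; requesting a late
#' stage without its upstream outputs fails with a message naming the
#' stage to run.
#'
#' @param config A [cohort_config()]; its seed drives every stochastic
#'   stage.
#' @param out_dir Output directory.
#' @param stages Subset of stages to run (default: all, in order).
#' @param n_sims Random placements for the overlap null (default 100).
#' @param overwrite Re-run stages whose outputs exist (default FALSE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = .stage_order,
                         n_sims = 100, overwrite = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  stages <- match.arg(stages, .stage_order, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  done <- character()

  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  fresh <- function(marker) overwrite || !file.exists(marker)

  if ("simulate" %in% stages &&
      fresh(file.path(out_dir, "inputs", "caller_a.bed"))) {
    cohort <- generate_cohort(config)
    write_cohort(cohort, file.path(out_dir, "inputs"))
    done <- c(done, "simulate")
  }

  if ("consensus" %in% stages &&
      fresh(file.path(out_dir, "consensus", "consensus.tsv"))) {
    inp <- .read_inputs(out_dir)
    res <- build_consensus(inp$calls_a, inp$calls_b, inp$samples)
    d <- stage_dir("consensus")
    write_tsv_commented(res$consensus$regions,
                        file.path(d, "consensus.tsv"), seed)
    write_bed(res$consensus$regions[, c("chrom", "start", "end", "cnvr_id",
                                        "class")],
              file.path(d, "consensus.bed"), seed)
    write_tsv_commented(res$consensus$copies, file.path(d, "copies.tsv"),
                        seed)
    write_tsv_commented(glance(res), file.path(d, "summary.tsv"), seed)
    write_tsv_commented(res$outliers$counts, file.path(d, "outliers.tsv"),
                        seed)
    write_tsv_commented(res$outliers$mds, file.path(d, "outlier_mds.tsv"),
                        seed)
    write_tsv_commented(tibble(sample = res$retained_samples),
                        file.path(d, "retained_samples.tsv"), seed)
    done <- c(done, "consensus")
  }

  if ("null_overlap" %in% stages &&
      fresh(file.path(out_dir, "null_overlap", "null_overlap.tsv"))) {
    inp <- .read_inputs(out_dir)
    cons <- .read_consensus(out_dir)
    b_merged <- merge_calls_to_cnvr(inp$calls_b)
    nul <- expected_overlap(cons$regions, b_merged$regions, inp$layout,
                            n_sims = n_sims, seed = seed)
    d <- stage_dir("null_overlap")
    write_tsv_commented(glance(nul), file.path(d, "null_overlap.tsv"), seed)
    done <- c(done, "null_overlap")
  }

  if ("annotate" %in% stages &&
      fresh(file.path(out_dir, "annotate", "annotated.tsv"))) {
    inp <- .read_inputs(out_dir)
    cons <- .read_consensus(out_dir)
    d <- stage_dir("annotate")
    ann <- flag_novel(cons, inp$known) |>
      mutate(frequency_pct = carrier_frequency(.data$carrier_count,
                                               cons$n_samples))
    write_tsv_commented(ann, file.path(d, "annotated.tsv"), seed)
    by_group <- cons$copies |>
      left_join(inp$samples, by = "sample") |>
      distinct(.data$cnvr_id, .data$group) |>
      left_join(cons$regions, by = "cnvr_id")
    sh <- population_sharing(by_group, inp$layout)
    write_tsv_commented(sh$venn, file.path(d, "sharing_venn.tsv"), seed)
    dens <- density_by_chromosome(cons, inp$calls_a, inp$layout)
    write_tsv_commented(dens, file.path(d, "density.tsv"), seed)
    wc <- window_correlation(left_join(inp$calls_a, inp$samples,
                                       by = "sample"), inp$layout)
    write_tsv_commented(as_tibble(wc, rownames = "population"),
                        file.path(d, "window_correlation.tsv"), seed)
    done <- c(done, "annotate")
  }

  if ("taghap" %in% stages &&
      fresh(file.path(out_dir, "taghap", "tagged_cnvrs.tsv"))) {
    inp <- .read_inputs(out_dir)
    cons <- .read_consensus(out_dir)
    snps <- read_vcf_phased(.need_file(inp$snps_path, "simulate"))
    qc <- snp_qc(snps)
    tags <- tag_cnvrs(cons, qc$snps, inp$layout)
    d <- stage_dir("taghap")
    write_tsv_commented(tidy(tags), file.path(d, "tags.tsv"), seed)
    write_tsv_commented(tags$cnvrs, file.path(d, "tagged_cnvrs.tsv"), seed)
    write_tsv_commented(qc$report, file.path(d, "snp_qc.tsv"), seed)
    done <- c(done, "taghap")
  }

  if ("selection" %in% stages &&
      fresh(file.path(out_dir, "selection", "joint.tsv"))) {
    inp <- .read_inputs(out_dir)
    cons <- .read_consensus(out_dir)
    tagged <- read_tsv_commented(
      .need_file(file.path(out_dir, "taghap", "tagged_cnvrs.tsv"), "taghap"))
    d <- stage_dir("selection")
    flanked <- flank_regions(cons, inp$layout)
    tab <- snp_region_table(inp$scores, flanked)
    enr <- chi_square(tab)
    write_tsv_commented(dplyr::bind_cols(tidy(enr) |>
                                           tidyr::pivot_wider(
                                             names_from = c("row", "column"),
                                             values_from = "count"),
                                         glance(enr)),
                        file.path(d, "snp_table.tsv"), seed)
    sel <- flag_selected(cons, inp$scores, inp$layout)
    st <- cnv_state_by_selection(cons, sel)
    write_tsv_commented(
      dplyr::bind_cols(as_tibble(st$table, rownames = "row"),
                       st$row_summary["mean_cnv_frequency_pct"]),
      file.path(d, "state_table.tsv"), seed)
    n_tag <- sum(tagged$tagged); n_sel <- sum(sel$selected)
    n_tot <- nrow(cons$regions)
    jt <- if (n_tag %in% c(0, n_tot) || n_sel %in% c(0, n_tot)) {
      # degenerate margin: independence test undefined on this cohort
      tibble(observed = sum(tagged$tagged & sel$selected),
             expected = joint_expected(n_tag, n_sel, n_tot)$expected,
             statistic = NA_real_, p_value = NA_real_, method = "none")
    } else {
      joint_excess_test(sum(tagged$tagged & sel$selected), n_tag, n_sel,
                        n_tot)
    }
    write_tsv_commented(jt, file.path(d, "joint.tsv"), seed)
    done <- c(done, "selection")
  }

  if ("popstruct" %in% stages &&
      fresh(file.path(out_dir, "popstruct", "pca.tsv"))) {
    inp <- .read_inputs(out_dir)
    cons <- .read_consensus(out_dir)
    retained <- read_tsv_commented(
      file.path(out_dir, "consensus", "retained_samples.tsv"))
    roster <- filter(inp$samples, .data$sample %in% retained$sample)
    d <- stage_dir("popstruct")
    pca <- cnv_pca(cons, k = min(10, nrow(roster) - 1), samples = roster)
    write_tsv_commented(pca$scores, file.path(d, "pca.tsv"), seed)
    fst <- fst_deletions(cons, roster)
    write_tsv_commented(as_tibble(fst$pairwise, rownames = "population"),
                        file.path(d, "fst_pairwise.tsv"), seed)
    hi <- if (sum(!is.na(fst$per_locus$fst)) >= 10) {
      high_fst_cnvrs(fst)
    } else {
      # too few defined loci for a stable outlier threshold
      mutate(fst$per_locus[, c("cnvr_id", "fst")], z = NA_real_,
             high_fst = NA)
    }
    loci <- left_join(hi, cons$regions[, c("cnvr_id", "chrom", "start",
                                           "end")], by = "cnvr_id")
    write_tsv_commented(loci, file.path(d, "fst_loci.tsv"), seed)
    done <- c(done, "popstruct")
  }

  manifest <- list(
    tool = "cnvrpipe",
    version = as.character(packageVersion("cnvrpipe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stages_run = done,
    parameters = config[!(names(config) %in% c("layout", "populations"))],
    layout = as.list(setNames(config$layout$length, config$layout$chrom)),
    digests = as.list(tools::md5sum(sort(list.files(
      out_dir, recursive = TRUE, full.names = TRUE,
      pattern = "\\.(tsv|bed|vcf)$")))))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
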