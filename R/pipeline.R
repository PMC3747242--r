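#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for the `run_*` stages. All
#' thresholds default to the standard analysis: 300-bp summit window, score
#' thresholds 6 (High) / 3 (Medium), +/-10 kb TSS assignment window,
#' fold-change cutoff 1.5 and t-test p cutoff 0.1.
#'
#' @param peaks_m,peaks_f narrowPeak paths for the two condition peak sets.
#' @param rxr_track_m,rxr_track_f coverage paths (bedGraph/wiggle) for the
#'   binding-factor ChIP in each condition.
#' @param pol2_track_m,pol2_track_f coverage paths for the Pol2 ChIP.
#' @param genes refFlat path.
#' @param expression optional expression TSV path; when `NULL`,
#'   [run_integrate()] skips the expression stage with a warning.
#' @param out_dir optional output directory; when given, the stages write
#'   their TSV/JSON outputs there.
#' @param score a [score_config()].
#' @param assign_mode,up,down peak-to-gene assignment rule
#'   (see [assign_genes()]).
#' @param fc_cutoff,p_cutoff expression screen cutoffs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(peaks_m, peaks_f, rxr_track_m, rxr_track_f,
                            pol2_track_m, pol2_track_f, genes,
                            expression = NULL, out_dir = NULL,
                            score = score_config(),
                            assign_mode = c("tss_window", "nearest_tss"),
                            up = 10000, down = 10000,
                            fc_cutoff = 1.5, p_cutoff = 0.1) {
  assign_mode <- match.arg(assign_mode)
  if (fc_cutoff <= 0 || p_cutoff <= 0) {
    stop_dimorph("pipeline_config: cutoffs must be positive")
  }
  structure(list(peaks_m = peaks_m, peaks_f = peaks_f,
                 rxr_track_m = rxr_track_m, rxr_track_f = rxr_track_f,
                 pol2_track_m = pol2_track_m, pol2_track_f = pol2_track_f,
                 genes = genes, expression = expression, out_dir = out_dir,
                 score = score, assign_mode = assign_mode, up = up,
                 down = down, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff),
            class = "pipeline_config")
}

#' Pipeline configuration for a fixture bundle directory
#'
#' Maps the standard file names written by [write_fixture_bundle()] /
#' [run_simulate()] onto a [pipeline_config()].
#'
#' @param dir bundle directory.
#' @param ... passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
bundle_pipeline_config <- function(dir, ...) {
  p <- function(f) file.path(dir, f)
  expr <- p("expression.tsv")
  pipeline_config(
    peaks_m = p("rxr_peaks_male.narrowPeak"),
    peaks_f = p("rxr_peaks_female.narrowPeak"),
    rxr_track_m = p("rxr_coverage_male.bedGraph"),
    rxr_track_f = p("rxr_coverage_female.bedGraph"),
    pol2_track_m = p("pol2_coverage_male.bedGraph"),
    pol2_track_f = p("pol2_coverage_female.bedGraph"),
    genes = p("genes.refFlat"),
    expression = if (file.exists(expr)) expr else NULL,
    ...
  )
}

#' Generate a synthetic fixture bundle (pipeline stage)
#'
#' Thin wrapper over [write_fixture_bundle()].
#'
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory.
#' @return The file manifest tibble, invisibly.
#' @export
run_simulate <- function(sim_config, out_dir) {
  stopifnot(inherits(sim_config, "simulation_config"))
  write_fixture_bundle(sim_config, out_dir)
}

# internal: read all pipeline inputs once
load_pipeline_inputs <- function(pcfg) {
  for (f in c("peaks_m", "peaks_f", "rxr_track_m", "rxr_track_f",
              "pol2_track_m", "pol2_track_f", "genes")) {
    if (!file.exists(pcfg[[f]])) {
      stop_dimorph("pipeline: missing input file for '%s': %s", f, pcfg[[f]])
    }
  }
  list(
    peaks_m = read_peaks(pcfg$peaks_m),
    peaks_f = read_peaks(pcfg$peaks_f),
    rxr_m = read_coverage(pcfg$rxr_track_m),
    rxr_f = read_coverage(pcfg$rxr_track_f),
    pol2_m = read_coverage(pcfg$pol2_track_m),
    pol2_f = read_coverage(pcfg$pol2_track_f),
    genes = read_gene_models(pcfg$genes)
  )
}

# internal: union of the two condition peak sets (shared peaks once)
union_peaks <- function(peaks_m, peaks_f) {
  u <- bind_rows(mutate(peaks_m, .set = "m"), mutate(peaks_f, .set = "f")) |>
    group_by(.data$chrom, .data$start, .data$end, .data$summit, .data$name) |>
    summarise(height = max(.data$height), score = first(.data$score),
              strand = first(.data$strand),
              in_m = any(.data$.set == "m"), in_f = any(.data$.set == "f"),
              .groups = "drop")
  u <- u |> mutate(name = uniquify_names(.data$name)) |>
    select("chrom", "start", "end", "name", "score", "strand", "height",
           "summit", "in_m", "in_f") |>
    arrange(.data$chrom, .data$start)
  u
}

#' Score peaks and genes (pipeline stage)
#'
#' Reads both condition peak sets, scores the union of peaks against the
#' binding-factor tracks, scores every gene body against the Pol2 tracks,
#' and tabulates High/Medium/Low strata per condition set. When
#' `out_dir` is set, writes `scored_peaks.tsv`, `gene_scores.tsv` and
#' `strata_summary.tsv`.
#'
#' @param pcfg a [pipeline_config()].
#' @return List of class `dimorphism_scores`: `scored_peaks` (union, with
#'   `in_m`/`in_f` membership flags), `gene_scores`, `strata`, `overlap`
#'   (the common/unique classification of the two sets), `timing`.
#' @export
run_score <- function(pcfg) {
  stopifnot(inherits(pcfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  inp <- load_pipeline_inputs(pcfg)
  u <- union_peaks(inp$peaks_m, inp$peaks_f)
  scored <- score_peaks(u, inp$rxr_m, inp$rxr_f, pcfg$score)
  gene_scores <- score_genes_pol2(inp$genes, inp$pol2_m, inp$pol2_f, pcfg$score)
  overlap <- classify_overlap(inp$peaks_m, inp$peaks_f)
  strata <- bind_rows(
    scored |> filter(.data$in_m) |> mutate(set = "male"),
    scored |> filter(.data$in_f) |> mutate(set = "female")
  ) |>
    group_by(.data$set, .data$stratum) |>
    summarise(n = n(), .groups = "drop")
  out <- structure(list(scored_peaks = scored, gene_scores = gene_scores,
                        strata = strata, overlap = overlap, genes = inp$genes,
                        timing = proc.time()[["elapsed"]] - t0),
                   class = "dimorphism_scores")
  if (!is.null(pcfg$out_dir)) {
    dir.create(pcfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(select(scored, -"in_m", -"in_f"),
                     file.path(pcfg$out_dir, "scored_peaks.tsv"))
    readr::write_tsv(gene_scores, file.path(pcfg$out_dir, "gene_scores.tsv"))
    readr::write_tsv(strata, file.path(pcfg$out_dir, "strata_summary.tsv"))
  }
  out
}

#' Call dimorphic genes (pipeline stage)
#'
#' Runs [run_score()] (or reuses its result), assigns peaks to genes with
#' the configured rule, and applies the combined binding + Pol2 criterion
#' ([call_dimorphic_genes()]). When `out_dir` is set, writes
#' `dimorphism_calls.tsv`.
#'
#' @param pcfg a [pipeline_config()].
#' @param scores optional [run_score()] result to reuse.
#' @return List of class `dimorphism_result`: the `dimorphism_scores`
#'   fields plus `assignments` and `calls`.
#' @export
run_classify <- function(pcfg, scores = NULL) {
  scores <- scores %||% run_score(pcfg)
  t0 <- proc.time()[["elapsed"]]
  assignments <- assign_genes(scores$scored_peaks, scores$genes,
                              mode = pcfg$assign_mode,
                              up = pcfg$up, down = pcfg$down)
  calls <- call_dimorphic_genes(scores$scored_peaks, assignments,
                                scores$gene_scores, pcfg$score)
  out <- structure(c(unclass(scores),
                     list(assignments = assignments, calls = calls,
                          classify_timing = proc.time()[["elapsed"]] - t0)),
                   class = "dimorphism_result")
  if (!is.null(pcfg$out_dir)) {
    dir.create(pcfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- calls |>
      mutate(supporting_peaks = map_chr(.data$supporting_peaks,
                                        paste, collapse = ",")) |>
      select("gene_id", "call", "n_supporting_peaks", "supporting_peaks",
             "best_peak_score", "pol2_score")
    readr::write_tsv(flat, file.path(pcfg$out_dir, "dimorphism_calls.tsv"))
  }
  out
}

#' Integrate expression and build the run report (pipeline stage)
#'
#' Runs [run_classify()] (or reuses its result), screens the expression
#' matrix and intersects it with the chromatin calls
#' ([integrate_three_way()]). Without an expression file the integration is
#' skipped with a warning and only the chromatin calls are reported. When
#' `out_dir` is set, writes `expression_records.tsv`,
#' `integrated_calls.tsv` and `run_report.json`.
#'
#' @param pcfg a [pipeline_config()].
#' @param classified optional [run_classify()] result to reuse.
#' @return A `dimorphism_result` with `expression`, `integrated` and
#'   `report` fields added (the latter a `run_report` list).
#' @export
run_integrate <- function(pcfg, classified = NULL) {
  res <- classified %||% run_classify(pcfg)
  expr_records <- NULL
  integrated <- NULL
  if (is.null(pcfg$expression)) {
    rlang::warn("run_integrate: no expression file configured; integration skipped")
  } else {
    expr <- read_expression(pcfg$expression)
    expr_records <- differential_expression(expr, fc_cutoff = pcfg$fc_cutoff,
                                            p_cutoff = pcfg$p_cutoff)
    integrated <- integrate_three_way(res$calls, expr_records)
  }
  report <- build_run_report(pcfg, res, expr_records, integrated)
  res$expression <- expr_records
  res$integrated <- integrated
  res$report <- report
  class(res) <- "dimorphism_result"
  if (!is.null(pcfg$out_dir)) {
    dir.create(pcfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(expr_records)) {
      readr::write_tsv(expr_records,
                       file.path(pcfg$out_dir, "expression_records.tsv"))
      readr::write_tsv(integrated,
                       file.path(pcfg$out_dir, "integrated_calls.tsv"))
    }
    jsonlite::write_json(report_for_json(report),
                         file.path(pcfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Run the whole pipeline
#'
#' Convenience meta-stage: score, classify and integrate in order.
#'
#' @param pcfg a [pipeline_config()].
#' @return A `dimorphism_result`.
#' @export
run_pipeline <- function(pcfg) run_integrate(pcfg)

# internal: assemble the run report
build_run_report <- function(pcfg, res, expr_records, integrated) {
  ov <- res$overlap$summary
  strata_tab <- tidyr::pivot_wider(res$strata, names_from = "stratum",
                                   values_from = "n", values_fill = 0L)
  calls_n <- table(factor(res$calls$call,
                          c("male_dominant", "female_dominant", "none")))
  report <- list(
    parameters = list(
      window = pcfg$score$window,
      high_threshold = pcfg$score$high_threshold,
      medium_threshold = pcfg$score$medium_threshold,
      test_method = pcfg$score$test_method,
      assign_mode = pcfg$assign_mode, up = pcfg$up, down = pcfg$down,
      fc_cutoff = pcfg$fc_cutoff, p_cutoff = pcfg$p_cutoff
    ),
    counts = list(
      peaks_male = ov$common_a + ov$unique_a,
      peaks_female = ov$common_b + ov$unique_b,
      common_male = ov$common_a, unique_male = ov$unique_a,
      common_female = ov$common_b, unique_female = ov$unique_b,
      peaks_union = nrow(res$scored_peaks),
      genes_scored = nrow(res$gene_scores),
      male_dominant = as.integer(calls_n[["male_dominant"]]),
      female_dominant = as.integer(calls_n[["female_dominant"]]),
      integrated_male = if (is.null(integrated)) NA_integer_ else
        sum(integrated$final == "male"),
      integrated_female = if (is.null(integrated)) NA_integer_ else
        sum(integrated$final == "female")
    ),
    strata = strata_tab,
    timing_seconds = list(score = res$timing,
                          classify = res$classify_timing %||% NA_real_)
  )
  structure(report, class = "run_report")
}

# internal: JSON-friendly view of a run report
report_for_json <- function(report) {
  r <- unclass(report)
  r$strata <- as.data.frame(r$strata)
  r$timing_seconds <- NULL   # keep written reports byte-identical across runs
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  c_ <- x$counts
  cat(sprintf("  peaks: %d male (%d common / %d unique), %d female (%d / %d)\n",
              c_$peaks_male, c_$common_male, c_$unique_male,
              c_$peaks_female, c_$common_female, c_$unique_female))
  cat(sprintf("  calls: %d male-dominant, %d female-dominant\n",
              c_$male_dominant, c_$female_dominant))
  if (!is.na(c_$integrated_male %||% NA)) {
    cat(sprintf("  integrated (with expression): %d male, %d female\n",
                c_$integrated_male, c_$integrated_female))
  }
  invisible(x)
}

#' @export
print.dimorphism_result <- function(x, ...) {
  cat("<dimorphism_result>\n")
  cat(sprintf("  %d scored peaks, %d gene scores, %d dimorphic calls\n",
              nrow(x$scored_peaks), nrow(x$gene_scores),
              sum(x$calls$call != "none")))
  if (!is.null(x$integrated)) {
    cat(sprintf("  integrated: %d male, %d female\n",
                sum(x$integrated$final == "male"),
                sum(x$integrated$final == "female")))
  }
  invisible(x)
}

#' @rdname run_classify
#' @param x a `dimorphism_result`.
#' @param ... unused.
#' @method tidy dimorphism_result
#' @export
tidy.dimorphism_result <- function(x, ...) {
  out <- x$calls
  if (!is.null(x$integrated)) {
    out <- left_join(out, select(x$integrated, "gene_id", "rna_pass", "final"),
                     by = "gene_id")
  }
  as_tibble(out)
}

#' @rdname run_classify
#' @method glance dimorphism_result
#' @export
glance.dimorphism_result <- function(x, ...) {
  tibble(
    n_peaks = nrow(x$scored_peaks),
    n_genes = nrow(x$gene_scores),
    male_dominant = sum(x$calls$call == "male_dominant"),
    female_dominant = sum(x$calls$call == "female_dominant"),
    integrated_male = if (is.null(x$integrated)) NA_integer_ else
      sum(x$integrated$final == "male"),
    integrated_female = if (is.null(x$integrated)) NA_integer_ else
      sum(x$integrated$final == "female")
  )
}
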