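#' Read an expression matrix
#'
#' Expects a TSV whose first column is the gene identifier and whose
#' remaining columns are named `<condition>_<replicate>` (e.g. `M_1`,
#' `M_2`, `F_1`, ...), holding linear-scale expression intensities.
#'
#' @param path TSV path.
#' @return Tibble with `gene_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_dimorph("read_expression: no such file: %s", path)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1] <- "gene_id"
  df
}

# internal: sample columns for a condition prefix
condition_cols <- function(expr, cond) {
  cols <- grep(paste0("^", cond, "_"), names(expr), value = TRUE)
  if (length(cols) < 2) {
    stop_dimorph("differential_expression: need >= 2 replicate columns '%s_*'", cond)
  }
  cols
}

#' Differential expression screen between two conditions
#'
#' For each gene, computes the linear-scale condition means, the fold change
#' as larger mean over smaller mean (so `fold_change >= 1`, with `direction`
#' indicating which condition is higher), and an equal-variance two-sample
#' Student t-test on log2-transformed intensities (the scale on which
#' microarray noise is approximately homoscedastic; set
#' `var_equal = FALSE` for Welch). A gene *passes* when
#' `fold_change > fc_cutoff` and `p_value < p_cutoff`; no multiple-testing
#' correction is applied. Genes measured by several rows (probes) are
#' collapsed to the row with the highest overall mean intensity.
#'
#' A gene with zero variance in both groups and equal means has an undefined
#' t statistic and is reported with `p_value = 1`.
#'
#' @param expr expression tibble (see [read_expression()]); values must be
#'   positive, linear scale.
#' @param cond_m,cond_f column-name prefixes of the two conditions.
#' @param fc_cutoff fold-change cutoff (default 1.5, either direction).
#' @param p_cutoff raw t-test p-value cutoff (default 0.1).
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return Tibble of class `expression_records`: `gene_id`, `mean_m`,
#'   `mean_f`, `fold_change`, `direction` (`"M"`/`"F"`), `t_statistic`,
#'   `p_value`, `passes`.
#' @export
differential_expression <- function(expr, cond_m = "M", cond_f = "F",
                                    fc_cutoff = 1.5, p_cutoff = 0.1,
                                    var_equal = TRUE) {
  cols_m <- condition_cols(expr, cond_m)
  cols_f <- condition_cols(expr, cond_f)
  vals <- as.matrix(expr[, c(cols_m, cols_f)])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_dimorph("differential_expression: intensities must be finite and > 0")
  }
  # collapse duplicate gene ids to the probe with maximal mean intensity
  keep <- tibble(gene_id = expr$gene_id, .row = seq_len(nrow(expr)),
                 .mean = rowMeans(vals)) |>
    group_by(.data$gene_id) |>
    slice(which.max(.data$.mean)) |>
    ungroup()
  expr <- expr[keep$.row, , drop = FALSE]
  xm <- log2(as.matrix(expr[, cols_m]))
  xf <- log2(as.matrix(expr[, cols_f]))
  n1 <- ncol(xm); n2 <- ncol(xf)
  m1 <- rowMeans(xm); m2 <- rowMeans(xf)
  v1 <- apply(xm, 1, var); v2 <- apply(xf, 1, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  p <- 2 * pt(-abs(t_stat), df)
  degen <- !is.finite(t_stat)
  t_stat[degen & m1 == m2] <- 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0   # perfect separation with zero variance
  mean_m <- rowMeans(as.matrix(expr[, cols_m]))
  mean_f <- rowMeans(as.matrix(expr[, cols_f]))
  out <- tibble(
    gene_id = expr$gene_id,
    mean_m = mean_m, mean_f = mean_f,
    fold_change = pmax(mean_m, mean_f) / pmin(mean_m, mean_f),
    direction = if_else(mean_m >= mean_f, "M", "F"),
    t_statistic = t_stat,
    p_value = p
  ) |>
    mutate(passes = .data$fold_change > fc_cutoff & .data$p_value < p_cutoff) |>
    arrange(.data$gene_id)
  class(out) <- c("expression_records", class(out))
  out
}

#' Three-way integration of binding, transcription and expression
#'
#' Combines per-gene dimorphism calls (strong same-direction binding-site
#' and Pol2 scores, [call_dimorphic_genes()]) with the expression screen
#' ([differential_expression()]). The final call is `male` only when the
#' gene is `male_dominant` *and* its expression passes the fold-change and
#' p-value cutoffs with the male side higher; `female` mirrors this. Any
#' direction conflict, failed cutoff, or gene absent from the expression
#' table yields `none`, with all three pass flags reported.
#'
#' @param calls a `dimorphism_calls` tibble.
#' @param expression_records an `expression_records` tibble.
#' @return Tibble of class `integrated_calls`: `gene_id`, `rxr_pass`,
#'   `pol2_pass`, `rna_pass`, `rna_direction`, `final`
#'   (`"male"`/`"female"`/`"none"`).
#' @export
integrate_three_way <- function(calls, expression_records) {
  ex <- select(expression_records, "gene_id", "passes", "direction")
  out <- calls |>
    left_join(ex, by = "gene_id") |>
    mutate(
      rxr_pass = .data$n_supporting_peaks > 0,
      pol2_pass = .data$call != "none",
      rna_pass = !is.na(.data$passes) & .data$passes,
      rna_direction = .data$direction,
      final = case_when(
        .data$call == "male_dominant" & .data$rna_pass & .data$direction == "M" ~ "male",
        .data$call == "female_dominant" & .data$rna_pass & .data$direction == "F" ~ "female",
        .default = "none"
      )
    ) |>
    select("gene_id", "rxr_pass", "pol2_pass", "rna_pass", "rna_direction", "final")
  class(out) <- c("integrated_calls", class(out))
  out
}

#' Pair chromatin scores with expression fold changes
#'
#' Joins per-gene scores (either the best-magnitude peak score per gene or
#' the Pol2 gene score) with signed log2 expression fold changes
#' (positive = male-higher) and reports Pearson and Spearman correlations
#' over the shared genes. With concordant regulation the correlation is
#' positive: genes bound/transcribed more strongly in one sex tend to be
#' expressed more highly in that sex.
#'
#' @param scores tibble with `gene_id` and `score` columns (e.g.
#'   [score_genes_pol2()] output, or [score_peaks()] output joined to genes
#'   via [assign_genes()]); several rows per gene are collapsed to the
#'   best-magnitude score.
#' @param expression_records an `expression_records` tibble.
#' @return List of class `score_expression_cor` with `table` (tibble
#'   `gene_id`, `score`, `log2_fc`), `pearson`, `spearman`, `n`.
#'   Correlations are `NA` (with a warning) when fewer than 3 genes are
#'   shared.
#' @export
score_expression_correlation <- function(scores, expression_records) {
  if (!all(c("gene_id", "score") %in% names(scores))) {
    stop_dimorph("score_expression_correlation: scores needs gene_id and score columns")
  }
  best <- scores |>
    group_by(.data$gene_id) |>
    slice(which.max(abs(.data$score))) |>
    ungroup() |>
    select("gene_id", "score")
  tab <- inner_join(
    best,
    mutate(expression_records,
           log2_fc = if_else(.data$direction == "M", 1, -1) *
             log2(.data$fold_change)) |>
      select("gene_id", "log2_fc"),
    by = "gene_id")
  if (nrow(tab) == 0) stop_dimorph("score_expression_correlation: no shared genes")
  if (nrow(tab) < 3) {
    rlang::warn("score_expression_correlation: fewer than 3 shared genes; correlations undefined")
    pe <- NA_real_; sp <- NA_real_
  } else {
    pe <- cor(tab$score, tab$log2_fc, method = "pearson")
    sp <- cor(tab$score, tab$log2_fc, method = "spearman")
  }
  structure(list(table = tab, pearson = pe, spearman = sp, n = nrow(tab)),
            class = "score_expression_cor")
}

#' @export
print.score_expression_cor <- function(x, ...) {
  cat(sprintf("<score_expression_cor> %d genes; Pearson %.3f, Spearman %.3f\n",
              x$n, x$pearson, x$spearman))
  invisible(x)
}

#' @rdname score_expression_correlation
#' @param x a `score_expression_cor`.
#' @param ... unused.
#' @method glance score_expression_cor
#' @export
glance.score_expression_cor <- function(x, ...) {
  tibble(n = x$n, pearson = x$pearson, spearman = x$spearman)
}

#' @rdname score_expression_correlation
#' @method tidy score_expression_cor
#' @export
tidy.score_expression_cor <- function(x, ...) x$table
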