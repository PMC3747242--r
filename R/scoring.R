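#' Scoring configuration
#'
#' Bundles the tunable parameters of the dimorphism score.
#'
#' @param window width in bp of the counting window centered on each peak
#'   summit (even, default 300).
#' @param high_threshold score magnitude above which a peak or gene is
#'   called significantly dimorphic (strictly greater; default 6,
#'   corresponding to `p < 10^-6.4`).
#' @param medium_threshold lower edge of the Medium stratum (default 3,
#'   `p <= 10^-0.8`).
#' @param test_method `"conditional_binomial"` (default) or
#'   `"poisson_tail"`; see [poisson_difference_pvalue()].
#' @param p_floor smallest representable p-value; smaller values are clamped
#'   so the score stays finite.
#' @param lambda_min floor for the Poisson rate in the `poisson_tail`
#'   method, so a `(k, 0)` pair yields a finite p-value.
#' @return A list of class `score_config`.
#' @export
score_config <- function(window = 300, high_threshold = 6, medium_threshold = 3,
                         test_method = c("conditional_binomial", "poisson_tail"),
                         p_floor = 1e-300, lambda_min = 1) {
  test_method <- match.arg(test_method)
  if (window <= 0 || window %% 2 != 0) {
    stop_dimorph("score_config: window must be even and > 0")
  }
  if (!(medium_threshold > 0 && medium_threshold < high_threshold)) {
    stop_dimorph("score_config: need 0 < medium_threshold < high_threshold")
  }
  if (p_floor <= 0 || p_floor >= 1) stop_dimorph("score_config: p_floor must be in (0,1)")
  if (lambda_min <= 0) stop_dimorph("score_config: lambda_min must be > 0")
  structure(list(window = window, high_threshold = high_threshold,
                 medium_threshold = medium_threshold, test_method = test_method,
                 p_floor = p_floor, lambda_min = lambda_min),
            class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat("<score_config>\n")
  cat(sprintf("  window: %d bp, thresholds: high > %g, medium >= %g\n",
              x$window, x$high_threshold, x$medium_threshold))
  cat(sprintf("  test: %s (p_floor %g, lambda_min %g)\n",
              x$test_method, x$p_floor, x$lambda_min))
  invisible(x)
}

#' Counting window centered on a peak summit
#'
#' Returns the `[summit - window/2, summit + window/2)` interval per summit,
#' clipped at position 0 (the right edge is kept, so a clipped window is
#' narrower than `window`).
#'
#' @param peaks peak tibble (needs `chrom`, `summit`), or a numeric vector
#'   of summit positions.
#' @param window window width in bp (even).
#' @return Tibble with columns `chrom` (if available), `start`, `end`.
#' @export
summit_window <- function(peaks, window = 300) {
  if (window <= 0 || window %% 2 != 0) {
    stop_dimorph("summit_window: window must be even and > 0")
  }
  summit <- if (is.numeric(peaks)) peaks else peaks$summit
  half <- window %/% 2
  out <- tibble(start = pmax(summit - half, 0), end = summit + half)
  if (!is.numeric(peaks) && "chrom" %in% names(peaks)) {
    out <- tibble(chrom = peaks$chrom, start = out$start, end = out$end)
  }
  out
}

# internal: direction of the normalized excess: "a", "b" or "none"
count_direction <- function(k_a, k_b, norm_a, norm_b) {
  ra <- k_a / norm_a
  rb <- k_b / norm_b
  case_when(ra > rb ~ "a", ra < rb ~ "b", .default = "none")
}

#' p-value for a difference between two Poisson counts
#'
#' Compares two read counts assumed Poisson, after scaling by the library
#' sizes `norm_a`, `norm_b`. Two variants are implemented (vectorized over
#' counts):
#'
#' * `conditional_binomial` (default): the exact conditional test for the
#'   ratio of two Poisson rates. Given the total `n = k_a + k_b`, the count
#'   on the stronger (normalized) side is Binomial(`n`, `p0`) under the
#'   null, with `p0` that side's share of the total library size; the
#'   p-value is the one-sided upper binomial tail in the direction of the
#'   observed excess. This variant is calibrated: under the null the
#'   probability of a p-value below `a` is at most `a` per direction.
#' * `poisson_tail`: treats the smaller normalized count (rescaled to the
#'   larger side's library, floored at `lambda_min`) as a known Poisson
#'   rate and computes `P(X >= k_max)`. Simpler, but anticonservative for
#'   moderate rates because it ignores the noise in the reference count.
#'
#' Results are floored at `p_floor`. Two equal-rate counts give p close to
#' 0.5-1; `(0, 0)` gives p = 1.
#'
#' @param k_a,k_b non-negative integer counts (vectors).
#' @param norm_a,norm_b positive library-size normalizers.
#' @param method `"conditional_binomial"` or `"poisson_tail"`.
#' @param p_floor,lambda_min see [score_config()].
#' @return p-values in `(0, 1]`.
#' @export
poisson_difference_pvalue <- function(k_a, k_b, norm_a = 1, norm_b = 1,
                                      method = c("conditional_binomial", "poisson_tail"),
                                      p_floor = 1e-300, lambda_min = 1) {
  method <- match.arg(method)
  if (any(k_a < 0) || any(k_b < 0)) stop_dimorph("poisson_difference_pvalue: negative count")
  if (any(k_a != round(k_a)) || any(k_b != round(k_b))) {
    stop_dimorph("poisson_difference_pvalue: counts must be integers")
  }
  if (any(norm_a <= 0) || any(norm_b <= 0)) {
    stop_dimorph("poisson_difference_pvalue: normalizers must be > 0")
  }
  m <- max(length(k_a), length(k_b))
  k_a <- rep_len(k_a, m); k_b <- rep_len(k_b, m)
  norm_a <- rep_len(norm_a, m); norm_b <- rep_len(norm_b, m)
  a_strong <- k_a / norm_a >= k_b / norm_b
  k_max <- if_else(a_strong, k_a, k_b)
  k_min <- if_else(a_strong, k_b, k_a)
  if (method == "poisson_tail") {
    norm_ratio <- if_else(a_strong, norm_a / norm_b, norm_b / norm_a)
    lambda <- pmax(k_min * norm_ratio, lambda_min)
    p <- ppois(k_max - 1, lambda, lower.tail = FALSE)
  } else {
    n <- k_a + k_b
    p0 <- if_else(a_strong, norm_a, norm_b) / (norm_a + norm_b)
    p <- pbinom(k_max - 1, n, p0, lower.tail = FALSE)
  }
  pmin(pmax(p, p_floor), 1)
}

#' Signed, log-scaled dimorphism score
#'
#' Transforms a p-value into the signed score
#' `score = +/- log2(-10 * log10(p))`, positive when condition A (male) has
#' the stronger normalized signal and negative when condition B (female)
#' does. When `-10*log10(p) <= 1` (p close to 1) or no direction can be
#' determined, the score is clamped to 0 so the logarithm stays defined;
#' this only affects clearly non-significant comparisons. A score above 6
#' corresponds to `p < 10^-6.4`, a magnitude of at least 3 to
#' `p <= 10^-0.8`.
#'
#' @param p p-values in `(0, 1]`.
#' @param direction `"a_stronger"`, `"b_stronger"` or `"none"` (recycled).
#' @return Numeric scores.
#' @export
signed_score <- function(p, direction = "a_stronger") {
  if (any(p <= 0 | p > 1)) stop_dimorph("signed_score: p must be in (0, 1]")
  m <- max(length(p), length(direction))
  p <- rep_len(p, m)
  direction <- rep_len(direction, m)
  if (!all(direction %in% c("a_stronger", "b_stronger", "none", "a", "b"))) {
    stop_dimorph("signed_score: invalid direction")
  }
  q <- -10 * log10(p)
  sign <- case_when(direction %in% c("a_stronger", "a") ~ 1,
                    direction %in% c("b_stronger", "b") ~ -1,
                    .default = 0)
  if_else(q <= 1 | sign == 0, 0, sign * log2(pmax(q, 1)))
}

#' Stratify a score magnitude into High / Medium / Low
#'
#' High when `|score| > high_threshold`, Medium when
#' `medium_threshold <= |score| <= high_threshold`, Low otherwise (both
#' boundaries fall in Medium; High is strict, matching "a score > 6 is
#' significant").
#'
#' @param score numeric scores (sign is ignored).
#' @param config a [score_config()].
#' @return Character vector in `c("High", "Medium", "Low")`.
#' @export
stratify_score <- function(score, config = score_config()) {
  a <- abs(score)
  case_when(a > config$high_threshold ~ "High",
            a >= config$medium_threshold ~ "Medium",
            .default = "Low")
}

# internal: shared scoring of count pairs -> p, score, stratum columns
score_count_pairs <- function(tbl, norm_a, norm_b, config) {
  dir <- count_direction(tbl$count_m, tbl$count_f, norm_a, norm_b)
  p <- poisson_difference_pvalue(tbl$count_m, tbl$count_f, norm_a, norm_b,
                                 method = config$test_method,
                                 p_floor = config$p_floor,
                                 lambda_min = config$lambda_min)
  score_vals <- signed_score(p, if_else(dir == "a", "a_stronger",
                                        if_else(dir == "b", "b_stronger", "none")))
  # .env-free assignment: local vectors deliberately named unlike any column
  tbl$norm_m <- rep_len(norm_a, nrow(tbl))
  tbl$norm_f <- rep_len(norm_b, nrow(tbl))
  tbl$p_value <- p
  tbl$score <- score_vals
  tbl$stratum <- stratify_score(score_vals, config)
  tbl
}

#' Score peaks for dimorphic occupancy between two conditions
#'
#' For each peak, reads from both condition tracks are counted in a window
#' centered on the summit ([summit_window()]), compared with
#' [poisson_difference_pvalue()] under library-size normalization, and
#' transformed to the signed score ([signed_score()]). Positive scores mean
#' stronger normalized occupancy in `track_m` (male), negative in `track_f`
#' (female). Peaks on chromosomes absent from a track are counted as 0
#' there, with a warning.
#'
#' @param peaks peak tibble (see [read_peaks()]).
#' @param track_m,track_f [coverage_track] objects for the two conditions.
#' @param config a [score_config()].
#' @return The input peaks with columns `count_m`, `count_f`, `norm_m`,
#'   `norm_f`, `p_value`, `score`, `stratum` appended; class `scored_peaks`.
#' @export
score_peaks <- function(peaks, track_m, track_f, config = score_config()) {
  check_peaks(peaks)
  win <- summit_window(peaks, config$window)
  out <- mutate(peaks,
                count_m = count_in_window(track_m, win, warn_missing_chrom = TRUE),
                count_f = count_in_window(track_f, win, warn_missing_chrom = TRUE))
  out <- score_count_pairs(out, track_m$library_size, track_f$library_size, config)
  class(out) <- c("scored_peaks", class(out))
  out
}

#' Score gene-body Pol2 occupancy between two conditions
#'
#' Counts reads over each gene's body — the genomic span between the
#' transcription start and end sites, strand-agnostic, i.e.
#' `[min(tss, tes), max(tss, tes) + 1)` — in both condition tracks and
#' applies the same Poisson comparison and signed score as [score_peaks()].
#' With RNA polymerase II tracks this score measures dimorphic
#' transcriptional engagement of the gene.
#'
#' @param genes gene-model tibble (see [read_gene_models()]).
#' @param track_m,track_f [coverage_track] objects (Pol2 samples).
#' @param config a [score_config()].
#' @return Tibble with `gene_id`, `chrom`, `span_start`, `span_end`,
#'   `count_m`, `count_f`, `norm_m`, `norm_f`, `p_value`, `score`,
#'   `stratum`; class `gene_scores`.
#' @export
score_genes_pol2 <- function(genes, track_m, track_f, config = score_config()) {
  check_genes(genes)
  span <- tibble(chrom = genes$chrom,
                 start = pmin(genes$tss, genes$tes),
                 end = pmax(genes$tss, genes$tes) + 1L)
  out <- tibble(gene_id = genes$gene_id, chrom = span$chrom,
                span_start = span$start, span_end = span$end,
                count_m = count_in_window(track_m, span, warn_missing_chrom = TRUE),
                count_f = count_in_window(track_f, span, warn_missing_chrom = TRUE))
  out <- score_count_pairs(out, track_m$library_size, track_f$library_size, config)
  class(out) <- c("gene_scores", class(out))
  out
}

#' Call sexually dimorphic genes from peak and Pol2 scores
#'
#' A gene is called `male_dominant` when it has at least one assigned peak
#' with score above `high_threshold` *and* its Pol2 gene-body score is above
#' `high_threshold`; `female_dominant` mirrors the rule with both scores
#' below `-high_threshold`; otherwise `none`. The conjunction of a strong
#' same-direction binding-site score and gene-body transcription score is
#' what distinguishes regulatory dimorphism from incidental binding. A gene
#' cannot satisfy both directions because the peak and Pol2 criteria are
#' sign-consistent.
#'
#' @param scored_peaks output of [score_peaks()].
#' @param peak_to_gene tibble `name` -> `gene_id` (see [assign_genes()]).
#' @param gene_scores output of [score_genes_pol2()].
#' @param config a [score_config()].
#' @return Tibble of class `dimorphism_calls` with one row per gene in
#'   `gene_scores` (plus peak-assigned genes missing from it, called `none`
#'   with a warning): `gene_id`, `call`, `n_supporting_peaks`,
#'   `supporting_peaks` (list), `best_peak_score`, `pol2_score`.
#' @export
call_dimorphic_genes <- function(scored_peaks, peak_to_gene, gene_scores,
                                 config = score_config()) {
  thr <- config$high_threshold
  assigned <- inner_join(peak_to_gene,
                         select(scored_peaks, "name", peak_score = "score"),
                         by = "name")
  per_gene <- assigned |>
    group_by(.data$gene_id) |>
    summarise(
      peaks_up = list(.data$name[.data$peak_score > thr]),
      peaks_down = list(.data$name[.data$peak_score < -thr]),
      best_peak_score = .data$peak_score[which.max(abs(.data$peak_score))[1]],
      .groups = "drop"
    )
  orphans <- setdiff(unique(assigned$gene_id), gene_scores$gene_id)
  if (length(orphans) > 0) {
    rlang::warn(sprintf(
      "call_dimorphic_genes: %d gene(s) with assigned peaks lack a Pol2 score; called 'none'",
      length(orphans)))
  }
  out <- tibble(gene_id = union(gene_scores$gene_id, orphans)) |>
    left_join(select(gene_scores, "gene_id", pol2_score = "score"), by = "gene_id") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(
      peaks_up = map(.data$peaks_up, ~ .x %||% character(0)),
      peaks_down = map(.data$peaks_down, ~ .x %||% character(0)),
      call = case_when(
        is.na(.data$pol2_score) ~ "none",
        lengths(.data$peaks_up) > 0 & .data$pol2_score > thr ~ "male_dominant",
        lengths(.data$peaks_down) > 0 & .data$pol2_score < -thr ~ "female_dominant",
        .default = "none"
      ),
      supporting_peaks = pmap(
        list(.data$call, .data$peaks_up, .data$peaks_down),
        function(cl, up, down) {
          if (cl == "male_dominant") up
          else if (cl == "female_dominant") down
          else character(0)
        }),
      n_supporting_peaks = lengths(.data$supporting_peaks)
    ) |>
    select("gene_id", "call", "n_supporting_peaks", "supporting_peaks",
           "best_peak_score", "pol2_score") |>
    arrange(.data$gene_id)
  class(out) <- c("dimorphism_calls", class(out))
  out
}
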