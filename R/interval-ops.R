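# internal: peaks/intervals tibble -> GRanges (coordinates converted to 1-based)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Classify peaks as common or unique between two conditions
#'
#' A peak of one set is *common* if it shares at least `min_overlap` bases
#' with at least one peak of the other set, and *unique* otherwise.
#' Coordinates are half-open, so `[100,200)` and `[200,300)` share zero
#' bases. Because peaks of the two sets need not pair one-to-one, the common
#' count is reported per set (`common_a` and `common_b` may differ).
#'
#' @param peaks_a,peaks_b peak tibbles (columns `chrom`, `start`, `end`,
#'   `name`; see [read_peaks()]).
#' @param min_overlap minimum shared bases (>= 1).
#' @return An object of class `overlap_classification`: a list with
#'   `peaks_a` and `peaks_b` (the inputs plus a logical `common` column) and
#'   a `summary` tibble with counts `common_a`, `unique_a`, `common_b`,
#'   `unique_b`. Use [tidy()] for per-peak status or [glance()] for the
#'   counts.
#' @export
classify_overlap <- function(peaks_a, peaks_b, min_overlap = 1) {
  if (min_overlap < 1) stop_dimorph("classify_overlap: min_overlap must be >= 1")
  mark <- function(x, y) {
    if (nrow(x) == 0) return(logical(0))
    if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
    hits <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y),
                                        minoverlap = min_overlap)
    seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
  }
  a <- mutate(peaks_a, common = mark(peaks_a, peaks_b))
  b <- mutate(peaks_b, common = mark(peaks_b, peaks_a))
  structure(list(
    peaks_a = a, peaks_b = b,
    summary = tibble(
      common_a = sum(a$common), unique_a = sum(!a$common),
      common_b = sum(b$common), unique_b = sum(!b$common)
    )
  ), class = "overlap_classification")
}

#' @export
print.overlap_classification <- function(x, ...) {
  s <- x$summary
  cat("<overlap_classification>\n")
  cat(sprintf("  set A: %d peaks (%d common, %d unique)\n",
              s$common_a + s$unique_a, s$common_a, s$unique_a))
  cat(sprintf("  set B: %d peaks (%d common, %d unique)\n",
              s$common_b + s$unique_b, s$common_b, s$unique_b))
  invisible(x)
}

#' @rdname classify_overlap
#' @param x an `overlap_classification`.
#' @param ... unused.
#' @method tidy overlap_classification
#' @export
tidy.overlap_classification <- function(x, ...) {
  bind_rows(
    mutate(select(x$peaks_a, "name", "chrom", "start", "end", "common"), set = "a"),
    mutate(select(x$peaks_b, "name", "chrom", "start", "end", "common"), set = "b")
  ) |>
    mutate(status = if_else(.data$common, "common", "unique")) |>
    select("set", "name", "chrom", "start", "end", "status")
}

#' @rdname classify_overlap
#' @method glance overlap_classification
#' @export
glance.overlap_classification <- function(x, ...) x$summary

#' Assign each peak a genomic feature class
#'
#' Classifies each peak by its summit position with precedence
#' TSS > TES > exon > intron > intergenic:
#'
#' * `TSS`: the summit lies within `tss_window` bp of some gene's
#'   transcription start site;
#' * `TES`: within `tes_window` bp of some transcription end site;
#' * `exon` / `intron`: the summit falls inside a gene body, in or out of an
#'   annotated exon;
#' * `intergenic`: none of the above.
#'
#' Every peak receives exactly one class; `gene_id` reports the gene that
#' triggered the class (the nearest such gene on ties), or `NA` for
#' intergenic peaks.
#'
#' @param peaks peak tibble (needs `chrom`, `name`, `summit`).
#' @param genes gene-model tibble (see [read_gene_models()]).
#' @param tss_window,tes_window half-width in bp of the TSS / TES class
#'   windows (distance `<=` window counts).
#' @return Tibble with columns `name`, `feature_class`, `gene_id`.
#' @export
annotate_feature <- function(peaks, genes, tss_window = 500, tes_window = 500) {
  check_genes(genes)
  n <- nrow(peaks)
  if (n == 0) {
    return(tibble(name = character(), feature_class = character(),
                  gene_id = character()))
  }
  summit_gr <- GenomicRanges::GRanges(peaks$chrom,
                                      IRanges::IRanges(peaks$summit + 1L, width = 1L))
  point_hit <- function(points) {
    # nearest gene anchor point per summit (exact |summit - point| distance)
    d <- rep(NA_real_, n)
    gid <- rep(NA_character_, n)
    for (ch in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == ch)
      gi <- which(genes$chrom == ch)
      if (length(gi) == 0) next
      dd <- abs(outer(peaks$summit[pi], points[gi], "-"))
      best <- apply(dd, 1, which.min)
      d[pi] <- dd[cbind(seq_along(pi), best)]
      gid[pi] <- genes$gene_id[gi[best]]
    }
    list(dist = d, gene = gid)
  }
  tss_hit <- point_hit(genes$tss)
  tes_hit <- point_hit(genes$tes)

  span_start <- pmin(genes$tss, genes$tes)
  span_end <- pmax(genes$tss, genes$tes) + 1L
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(span_start + 1L, span_end))
  body_hits <- GenomicRanges::findOverlaps(summit_gr, gene_gr, select = "first")

  exon_tbl <- tibble(
    gene_idx = rep(seq_len(nrow(genes)), lengths(genes$exon_starts)),
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts),
    end = unlist(genes$exon_ends)
  )
  in_exon_of <- rep(NA_integer_, n)
  if (nrow(exon_tbl) > 0) {
    exon_gr <- GenomicRanges::GRanges(exon_tbl$chrom,
                                      IRanges::IRanges(exon_tbl$start + 1L, exon_tbl$end))
    eh <- GenomicRanges::findOverlaps(summit_gr, exon_gr, select = "first")
    in_exon_of <- exon_tbl$gene_idx[eh]
  }

  feature_class <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)

  body_idx <- !is.na(body_hits)
  feature_class[body_idx] <- "intron"
  gene_id[body_idx] <- genes$gene_id[body_hits[body_idx]]
  exon_idx <- !is.na(in_exon_of)
  feature_class[exon_idx] <- "exon"
  gene_id[exon_idx] <- genes$gene_id[in_exon_of[exon_idx]]
  tes_idx <- !is.na(tes_hit$dist) & tes_hit$dist <= tes_window
  feature_class[tes_idx] <- "TES"
  gene_id[tes_idx] <- tes_hit$gene[tes_idx]
  tss_idx <- !is.na(tss_hit$dist) & tss_hit$dist <= tss_window
  feature_class[tss_idx] <- "TSS"
  gene_id[tss_idx] <- tss_hit$gene[tss_idx]

  tibble(name = peaks$name, feature_class = feature_class, gene_id = gene_id)
}

#' Assign peaks to genes
#'
#' Two assignment rules are offered:
#'
#' * `tss_window` (default): a peak is assigned to every gene whose
#'   transcription start site lies within `up` bp upstream to `down` bp
#'   downstream of the summit, in the gene's strand orientation, boundaries
#'   inclusive. This is the promoter/enhancer window rule (default
#'   +/- 10 kb).
#' * `nearest_tss`: each peak is assigned to the single gene with minimal
#'   `|summit - tss|` on the same chromosome (ties broken by the
#'   lexicographically smallest `gene_id`).
#'
#' @param peaks peak tibble (needs `chrom`, `name`, `summit`).
#' @param genes gene-model tibble.
#' @param mode `"tss_window"` or `"nearest_tss"`.
#' @param up,down window extent upstream / downstream of the TSS in bp
#'   (`tss_window` mode).
#' @return Tibble with columns `name`, `gene_id` (possibly several rows per
#'   peak in `tss_window` mode; peaks matching no gene are absent).
#' @export
assign_genes <- function(peaks, genes, mode = c("tss_window", "nearest_tss"),
                         up = 10000, down = 10000) {
  mode <- match.arg(mode)
  check_genes(genes)
  if (nrow(genes) == 0) stop_dimorph("assign_genes: empty gene list")
  if (up < 0 || down < 0) stop_dimorph("assign_genes: up/down must be >= 0")
  if (nrow(peaks) == 0) return(tibble(name = character(), gene_id = character()))
  summit_gr <- GenomicRanges::GRanges(peaks$chrom,
                                      IRanges::IRanges(peaks$summit + 1L, width = 1L))
  if (mode == "nearest_tss") {
    # ties resolved toward the smallest gene_id: order genes before matching
    g <- arrange(genes, .data$gene_id)
    gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$tss + 1L, width = 1L))
    out <- tibble(name = peaks$name, gene_id = NA_character_,
                  dist = NA_real_, summit = peaks$summit, chrom = peaks$chrom)
    for (ch in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == ch)
      gi <- which(g$chrom == ch)
      if (length(gi) == 0) next
      d <- abs(outer(peaks$summit[pi], g$tss[gi], "-"))
      best <- apply(d, 1, which.min)  # first minimum = smallest gene_id
      out$gene_id[pi] <- g$gene_id[gi[best]]
      out$dist[pi] <- d[cbind(seq_along(pi), best)]
    }
    return(select(filter(out, !is.na(.data$gene_id)), "name", "gene_id"))
  }
  # tss_window: gene window [tss - up, tss + down] strand-oriented, inclusive
  win_lo <- if_else(genes$strand == "-", genes$tss - down, genes$tss - up)
  win_hi <- if_else(genes$strand == "-", genes$tss + up, genes$tss + down)
  win_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(pmax(win_lo, 0) + 1L, win_hi + 1L))
  hits <- GenomicRanges::findOverlaps(summit_gr, win_gr)
  tibble(
    name = peaks$name[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct() |> arrange(.data$name, .data$gene_id)
}

#' Observed vs expected peak distribution over genomic categories
#'
#' Tests whether peaks distribute over categories (chromosomes, feature
#' classes, ...) in proportion to category length. Under the random-placement
#' null, a category of length `L` in a genome of length `G` should receive
#' `N * L / G` of the `N` peaks; each category is tested with a two-sided
#' exact binomial test.
#'
#' @param peaks peak tibble with a `category` column, or a character vector
#'   of per-peak categories.
#' @param category_lengths named numeric vector: genomic length per category.
#' @param genome_length total genome length; defaults to
#'   `sum(category_lengths)`.
#' @return Tibble with columns `category`, `observed`, `expected`,
#'   `p_value`, `direction` (`"enriched"`/`"depleted"`).
#' @export
distribution_test <- function(peaks, category_lengths, genome_length = NULL) {
  cats <- if (is.character(peaks)) peaks else peaks$category
  if (is.null(cats)) stop_dimorph("distribution_test: peaks needs a 'category' column")
  if (any(category_lengths <= 0)) stop_dimorph("distribution_test: zero-length category")
  genome_length <- genome_length %||% sum(category_lengths)
  if (sum(category_lengths) > genome_length + 1e-9) {
    stop_dimorph("distribution_test: category lengths exceed genome length")
  }
  n <- length(cats)
  if (n == 0) stop_dimorph("distribution_test: no peaks")
  obs <- table(factor(cats, levels = names(category_lengths)))
  tibble(
    category = names(category_lengths),
    observed = as.integer(obs),
    expected = unname(n * category_lengths / genome_length),
    p_value = map_dbl(seq_along(category_lengths), function(i) {
      binom.test(as.integer(obs[i]), n,
                 p = category_lengths[i] / genome_length)$p.value
    }),
    direction = unname(if_else(as.integer(obs) >= n * category_lengths / genome_length,
                               "enriched", "depleted"))
  )
}

#' Count peaks per height stratum
#'
#' Bins peak heights into right-open bins `[0, e1), [e1, e2), ...` plus an
#' overflow bin `[e_k, Inf)`; counts always sum to the number of peaks.
#'
#' @param peaks peak tibble with a `height` column, or a numeric vector of
#'   heights.
#' @param bin_edges strictly increasing positive edges.
#' @return Tibble with columns `bin` (label), `lower`, `upper`, `count`.
#' @export
stratify_peak_heights <- function(peaks, bin_edges) {
  h <- if (is.numeric(peaks)) peaks else peaks$height
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_dimorph("stratify_peak_heights: bin_edges must be strictly increasing")
  }
  lower <- c(0, bin_edges)
  upper <- c(bin_edges, Inf)
  counts <- vapply(seq_along(lower),
                   function(i) sum(h >= lower[i] & h < upper[i]), numeric(1))
  tibble(
    bin = sprintf("[%s,%s)", format(lower, trim = TRUE),
                  format(upper, trim = TRUE)),
    lower = lower, upper = upper, count = as.integer(counts)
  )
}
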