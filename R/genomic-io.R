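#' Read a peak file
#'
#' Reads called binding sites into a tibble. Two dialects are supported:
#'
#' * `narrowPeak` (ENCODE BED6+4): 10 tab-separated columns; the peak height
#'   is taken from column 7 (`signalValue`), interpreted as reads at the
#'   summit, and the summit from column 10 (0-based offset from `start`;
#'   `-1` means "unknown" and falls back to the interval midpoint).
#' * `bed_summit` (BED6): the score column is the height and the summit is
#'   the interval midpoint.
#'
#' All coordinates are 0-based half-open. Duplicate names are made unique by
#' suffixing `.2`, `.3`, ... to repeats. Gzipped files are read
#' transparently.
#'
#' @param path peak file path.
#' @param dialect `"narrowPeak"` or `"bed_summit"`.
#' @param coverage optional [coverage_track]; when given and a narrowPeak
#'   record has `signalValue <= 0`, the height is taken from the coverage at
#'   the summit instead.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `height`, `summit`, sorted by (`chrom`, `start`).
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed_summit"),
                       coverage = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_dimorph("read_peaks: no such file: %s", path)
  lines <- readr::read_lines(path)
  lines_idx <- seq_along(lines)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lines_idx <- lines_idx[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  height = numeric(), summit = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_needed <- if (dialect == "narrowPeak") 10L else 6L
  nf <- lengths(fields)
  if (any(nf < ncol_needed)) {
    bad <- lines_idx[which(nf < ncol_needed)[1]]
    stop_dimorph("read_peaks: line %d of %s has %d fields, expected %d",
                 bad, path, nf[which(nf < ncol_needed)[1]], ncol_needed)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (any(is.na(start)) || any(is.na(end))) {
    bad <- lines_idx[which(is.na(start) | is.na(end))[1]]
    stop_dimorph("read_peaks: non-numeric coordinate at line %d of %s", bad, path)
  }
  if (any(end <= start) || any(start < 0)) {
    bad <- lines_idx[which(end <= start | start < 0)[1]]
    stop_dimorph("read_peaks: invalid interval at line %d of %s", bad, path)
  }
  peaks <- tibble(
    chrom = get(1), start = start, end = end,
    name = uniquify_names(get(4)),
    score = suppressWarnings(as.numeric(get(5))),
    strand = get(6)
  )
  midpoint <- peaks$start + (peaks$end - peaks$start) %/% 2L
  if (dialect == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(get(7)))
    offset <- suppressWarnings(as.integer(get(10)))
    if (any(is.na(offset))) {
      bad <- lines_idx[which(is.na(offset))[1]]
      stop_dimorph("read_peaks: non-numeric summit offset at line %d of %s", bad, path)
    }
    summit <- if_else(offset < 0L, midpoint, peaks$start + offset)
    peaks$height <- signal
    peaks$summit <- summit
    if (!is.null(coverage)) {
      redo <- which(!is.na(signal) & signal <= 0)
      if (length(redo) > 0) {
        peaks$height[redo] <- count_in_window(
          coverage,
          tibble(chrom = peaks$chrom[redo], start = peaks$summit[redo],
                 end = peaks$summit[redo] + 1L))
      }
    }
  } else {
    peaks$height <- peaks$score
    peaks$summit <- midpoint
  }
  bad <- which(peaks$summit < peaks$start | peaks$summit >= peaks$end)
  if (length(bad) > 0) {
    stop_dimorph("read_peaks: summit outside interval at line %d of %s",
                 lines_idx[bad[1]], path)
  }
  arrange(peaks, .data$chrom, .data$start)
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_peaks()] for the narrowPeak dialect: coordinates, summits
#' and heights round-trip exactly. The p/q columns are written as -1
#' (unavailable).
#'
#' @param peaks peaks tibble (see [read_peaks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  check_peaks(peaks)
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format(score, trim = TRUE, scientific = FALSE),
                   strand,
                   format(peaks$height, trim = TRUE, scientific = FALSE,
                          digits = 15),
                   peaks$summit - peaks$start)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene models from a refFlat table
#'
#' Parses the 11-column UCSC refFlat format (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds). The
#' biological transcription start site (`tss`) is `txStart` for `+` strand
#' genes and `txEnd - 1` for `-` strand genes; `tes` is the opposite end, so
#' `tss > tes` in genome coordinates for `-` strand genes.
#'
#' @param path refFlat file path (tab-separated, optionally gzipped).
#' @return Tibble with columns `gene_id`, `symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `tss`, `tes`, and list-columns `exon_starts`,
#'   `exon_ends` (0-based half-open, sorted, non-overlapping).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_dimorph("read_gene_models: no such file: %s", path)
  df <- readr::read_tsv(
    path,
    col_names = c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds"),
    col_types = "cccciiiiicc", comment = "#", progress = FALSE
  )
  if (any(!df$strand %in% c("+", "-"))) {
    stop_dimorph("read_gene_models: strand must be '+' or '-'")
  }
  parse_pos <- function(s) as.integer(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
  exon_starts <- map(df$exonStarts, parse_pos)
  exon_ends <- map(df$exonEnds, parse_pos)
  nexp <- df$exonCount
  bad <- which(lengths(exon_starts) != nexp | lengths(exon_ends) != nexp)
  if (length(bad) > 0) {
    stop_dimorph("read_gene_models: exonCount mismatch for gene '%s' (record %d)",
                 df$name[bad[1]], bad[1])
  }
  tibble(
    gene_id = uniquify_names(df$name),
    symbol = df$geneName,
    chrom = df$chrom,
    strand = df$strand,
    tx_start = df$txStart,
    tx_end = df$txEnd,
    tss = if_else(df$strand == "+", df$txStart, df$txEnd - 1L),
    tes = if_else(df$strand == "+", df$txEnd - 1L, df$txStart),
    exon_starts = exon_starts,
    exon_ends = exon_ends
  )
}

#' Write gene models as refFlat
#'
#' @param genes tibble as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  check_genes(genes)
  join_pos <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- sprintf(
    "%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
    if ("symbol" %in% names(genes)) genes$symbol else genes$gene_id,
    genes$gene_id, genes$chrom, genes$strand,
    genes$tx_start, genes$tx_end, genes$tx_start, genes$tx_end,
    lengths(genes$exon_starts),
    map_chr(genes$exon_starts, join_pos),
    map_chr(genes$exon_ends, join_pos))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Discard PCR duplicates from read positions
#'
#' Retains at most `max_per_position` reads per (chromosome, 5' position,
#' strand) key — the standard PCR-duplicate rule for single-end ChIP-seq
#' where an excess of identical read starts reflects amplification rather
#' than occupancy. The default keeps two reads per key, i.e. reads appearing
#' more than twice at the same position on the same strand are discarded.
#' Input order of the surviving reads is preserved; only the 5' position
#' defines the key (read length is ignored).
#'
#' @param reads tibble with columns `chrom`, `pos`, `strand`.
#' @param max_per_position maximum reads kept per key (>= 1).
#' @return Filtered tibble of the same shape.
#' @export
deduplicate_reads <- function(reads, max_per_position = 2) {
  if (max_per_position < 1) stop_dimorph("deduplicate_reads: max_per_position must be >= 1")
  if (nrow(reads) == 0) return(reads)
  if (!all(c("chrom", "pos", "strand") %in% names(reads))) {
    stop_dimorph("deduplicate_reads: reads needs chrom/pos/strand columns")
  }
  key <- paste(reads$chrom, reads$pos, reads$strand, sep = "\r")
  nth <- stats::ave(seq_along(key), key, FUN = seq_along)
  reads[nth <= max_per_position, , drop = FALSE]
}
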