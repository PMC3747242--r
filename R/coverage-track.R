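#' Coverage tracks
#'
#' A `coverage_track` holds queryable per-base read coverage for one ChIP
#' sample, together with a library-size normalizer used when two samples are
#' compared. Internally each chromosome is a run-length-encoded vector
#' ([S4Vectors::Rle]); all user-facing coordinates are 0-based half-open, as
#' in BED. Two flavours are used in practice:
#'
#' * point-read tracks, where each read contributes 1 at its 5' position, so
#'   that a window sum is exactly a read count (the default everywhere in
#'   this package, and what the synthetic generator emits);
#' * base-coverage tracks (e.g. from extended-fragment wiggles), where a
#'   window sum is a coverage area rather than a read count.
#'
#' @param values named list of [S4Vectors::Rle] vectors, one per chromosome;
#'   element `i` of a vector is the value at 0-based position `i - 1`.
#' @param library_size positive number, total mapped reads in the sample.
#'   Used as the normalizer when comparing two conditions.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, library_size) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop_dimorph("coverage_track: 'values' must be a named list (one Rle per chromosome)")
  }
  values <- lapply(values, function(v) if (inherits(v, "Rle")) v else S4Vectors::Rle(v))
  if (any(vapply(values, function(v) any(S4Vectors::runValue(v) < 0), logical(1)))) {
    stop_dimorph("coverage_track: negative coverage value")
  }
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0) {
    stop_dimorph("coverage_track: library_size must be a single positive number")
  }
  structure(list(values = values, library_size = as.numeric(library_size)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x$values, length, numeric(1))
  cat("<coverage_track> ", length(lens), " chromosome(s), library size ",
      format(x$library_size, big.mark = ","), "\n", sep = "")
  for (ch in names(lens)) {
    cat("  ", ch, ": ", format(lens[[ch]], big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' @export
format.coverage_track <- function(x, ...) {
  sprintf("<coverage_track: %d chrom, N=%g>", length(x$values), x$library_size)
}

#' Build a point-read coverage track from read 5' positions
#'
#' Each read contributes 1 at its 5' position, so window sums over the result
#' are read counts. Strand is ignored for counting (reads of both strands
#' pile into the same track), matching strand-agnostic window counting.
#'
#' @param reads tibble with columns `chrom`, `pos` (0-based 5' position) and
#'   optionally `strand`.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximal read position + 1 per chromosome.
#' @param library_size normalizer; defaults to the number of reads.
#' @return A [coverage_track].
#' @export
track_from_reads <- function(reads, chrom_lengths = NULL, library_size = NULL) {
  if (nrow(reads) == 0 && is.null(chrom_lengths)) {
    stop_dimorph("track_from_reads: empty reads and no chrom_lengths given")
  }
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(reads$chrom)
  vals <- lapply(chroms, function(ch) {
    pos <- reads$pos[reads$chrom == ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(pos) + 1
    if (length(pos) == 0) return(S4Vectors::Rle(0L, len))
    IRanges::coverage(IRanges::IRanges(start = pos + 1L, width = 1L), width = len)
  })
  names(vals) <- chroms
  coverage_track(vals, library_size %||% max(nrow(reads), 1))
}

#' Read a coverage track from a wiggle or bedGraph file
#'
#' Parsing is delegated to [rtracklayer::import()], so UCSC fixedStep /
#' variableStep wiggle declarations (1-based) and bedGraph records (0-based
#' half-open) are both supported, including gzipped files. The imported
#' intervals are converted to the package's internal 0-based half-open
#' representation; querying outside any covered region returns 0.
#'
#' @param path file path (`.wig`, `.bedGraph`/`.bdg`, optionally `.gz`).
#' @param format `"auto"` (by extension), `"wiggle"` or `"bedGraph"`.
#' @param library_size optional normalizer; when `NULL`, the total signal
#'   (sum of value x width) is used, which equals the read count for
#'   point-read tracks.
#' @return A [coverage_track].
#' @export
read_coverage <- function(path, format = c("auto", "wiggle", "bedGraph"),
                          library_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_dimorph("read_coverage: no such file: %s", path)
  fmt <- switch(format,
    auto = {
      base <- sub("\\.gz$", "", path)
      if (grepl("\\.wig$", base, ignore.case = TRUE)) "wig" else "bedGraph"
    },
    wiggle = "wig",
    bedGraph = "bedGraph"
  )
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop_dimorph("read_coverage: cannot parse %s as %s (%s)",
                                     path, fmt, conditionMessage(e))
  )
  score <- as.numeric(S4Vectors::mcols(gr)$score)
  if (any(score < 0)) stop_dimorph("read_coverage: negative coverage value in %s", path)
  cov <- GenomicRanges::coverage(gr, weight = score)
  vals <- as.list(cov)
  total <- sum(score * BiocGenerics::width(gr))
  coverage_track(vals, library_size %||% max(total, 1))
}

#' Write a coverage track as bedGraph
#'
#' Zero-valued runs are omitted. The output round-trips through
#' [read_coverage()] to an identical track.
#'
#' @param track a [coverage_track].
#' @param path output path.
#' @param name track name for the bedGraph `track` line.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, name = "coverage") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    rl <- S4Vectors::runLength(v)
    rv <- S4Vectors::runValue(v)
    ends <- cumsum(as.numeric(rl))        # 0-based exclusive ends
    starts <- ends - as.numeric(rl)       # 0-based starts
    keep <- rv != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       format(rv[keep], trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Sum coverage over genomic windows
#'
#' Returns the sum of per-base values over each `[start, end)` window. On a
#' point-read track this is the read count in the window. Windows (or window
#' parts) outside any covered region contribute 0; a window on a chromosome
#' absent from the track returns 0.
#'
#' @param track a [coverage_track].
#' @param windows tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param warn_missing_chrom warn when a window's chromosome is absent from
#'   the track.
#' @return Numeric vector of window sums, one per row of `windows`.
#' @export
count_in_window <- function(track, windows, warn_missing_chrom = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  if (!all(c("chrom", "start", "end") %in% names(windows))) {
    stop_dimorph("count_in_window: windows needs chrom/start/end columns")
  }
  if (any(windows$end <= windows$start)) {
    stop_dimorph("count_in_window: end must exceed start")
  }
  out <- numeric(nrow(windows))
  missing_chroms <- character(0)
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    len <- length(v)
    s <- pmax(windows$start[idx] + 1, 1)  # 1-based inclusive
    e <- pmin(windows$end[idx], len)      # 1-based inclusive
    ok <- which(s <= e & s <= len)
    if (length(ok) > 0) {
      vw <- IRanges::Views(v, start = s[ok], end = e[ok])
      out[idx[ok]] <- IRanges::viewSums(vw)
    }
  }
  if (warn_missing_chrom && length(missing_chroms) > 0) {
    rlang::warn(sprintf("count_in_window: chromosome(s) absent from track, counted as 0: %s",
                        paste(unique(missing_chroms), collapse = ", ")))
  }
  out
}
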