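# Shared in-code fixtures: everything is built programmatically.

# a minimal peaks tibble
make_peaks <- function(chrom, start, end, name = NULL, summit = NULL,
                       height = 10) {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end),
    name = name %||% paste0("p", seq_len(n)),
    score = 0, strand = ".",
    height = rep_len(height, n),
    summit = as.integer(summit %||% (start + (end - start) %/% 2))
  )
}

# a two-gene annotation: one gene per strand, 2 exons each
make_genes <- function() {
  tibble::tibble(
    gene_id = c("geneA", "geneB"),
    symbol = c("GeneA", "GeneB"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    tx_start = c(10000L, 60000L),
    tx_end = c(20000L, 75000L),
    tss = c(10000L, 74999L),
    tes = c(19999L, 60000L),
    exon_starts = list(c(10000L, 15000L), c(60000L, 70000L)),
    exon_ends = list(c(12000L, 20000L), c(62000L, 75000L))
  )
}

# point-read track from explicit 0-based positions
make_track <- function(pos, chrom = "chr1", len = NULL, library_size = NULL) {
  track_from_reads(
    tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = "+"),
    chrom_lengths = stats::setNames(len %||% (max(pos) + 100), chrom[1]),
    library_size = library_size
  )
}

# independent term-by-term Poisson upper-tail summation (oracle):
# P(X >= k) for X ~ Poisson(lambda), summing the pmf recursively from k
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  log_term <- -lambda + k * log(lambda) - lgamma(k + 1)
  if (log_term < log(1e-320)) return(0)
  term <- exp(log_term)
  total <- term
  i <- k
  repeat {
    i <- i + 1
    term <- term * lambda / i
    total <- total + term
    if (term < total * 1e-17 && i > lambda) break
  }
  total
}

# independent binomial upper-tail summation: P(X >= k), X ~ Bin(n, p)
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  log_term <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  term <- exp(log_term)
  total <- term
  for (i in seq(k + 1, length.out = max(n - k, 0))) {
    term <- term * (n - i + 1) / i * p / (1 - p)
    total <- total + term
  }
  total
}

`%||%` <- function(x, y) if (is.null(x)) y else x
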