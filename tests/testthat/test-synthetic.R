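# compact study used throughout: 1 chromosome, 40 genes, 300 peaks
small_config <- function(seed = 42, n_peaks = 300, ...) {
  simulation_config(seed = seed, n_chromosomes = 1, chromosome_length = 2e6,
                    n_genes = 40, n_peaks = n_peaks, ...)
}

test_that("generated annotations are packed, stranded and reproducible", {
  cfg <- small_config()
  g <- generate_annotation(cfg)
  expect_equal(nrow(g), 40)
  expect_true(all(g$tx_end > g$tx_start))
  # pairwise non-overlapping (single chromosome, sorted construction)
  expect_true(all(g$tx_start[-1] > g$tx_end[-nrow(g)]))
  expect_equal(unique(g$strand), c("+", "-"))
  # strand convention
  expect_equal(g$tss[g$strand == "+"], g$tx_start[g$strand == "+"])
  expect_equal(g$tss[g$strand == "-"], g$tx_end[g$strand == "-"] - 1L)
  # exons tile within the gene and never overlap
  for (i in seq_len(nrow(g))) {
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    expect_true(length(es) >= 2 && length(es) <= 5)
    expect_true(all(ee > es))
    if (length(es) > 1) expect_true(all(es[-1] >= ee[-length(ee)]))
    expect_equal(es[1], g$tx_start[i])
    expect_equal(ee[length(ee)], g$tx_end[i])
  }
  expect_identical(g, generate_annotation(cfg))
  expect_error(generate_annotation(
    simulation_config(n_chromosomes = 1, chromosome_length = 1e6, n_genes = 1000)),
    "pack")
})

test_that("peak landscape plants the configured dimorphic structure", {
  cfg <- small_config()
  g <- generate_annotation(cfg)
  land <- generate_peak_landscape(cfg, g)
  truth <- land$truth$genes
  expect_equal(sum(truth$true_class == "male_dominant"), 4)     # 10% of 40
  expect_equal(sum(truth$true_class == "female_dominant"), 4)
  # every dominant gene's planted peak lies within 10 kb of its TSS
  planted <- dplyr::inner_join(
    dplyr::filter(land$truth$peaks, set == "planted"),
    dplyr::select(g, gene_id, tss), by = "gene_id")
  expect_true(all(abs(planted$summit - planted$tss) <= 10000))
  # planted rates are oriented by class
  pl <- dplyr::inner_join(planted, truth, by = "gene_id")
  m <- pl$true_class == "male_dominant"
  expect_true(all(pl$rate_m.x[m] > pl$rate_f.x[m]))
  expect_true(all(pl$rate_f.x[!m] > pl$rate_m.x[!m]))
  # summits at interval midpoints
  expect_true(all(land$peaks_m$summit ==
                    land$peaks_m$start + (land$peaks_m$end - land$peaks_m$start) %/% 2))
  expect_identical(land$peaks_m, generate_peak_landscape(cfg, g)$peaks_m)
})

test_that("shared fraction extremes drive the overlap classification", {
  g <- generate_annotation(small_config())
  all_shared <- generate_peak_landscape(
    small_config(fraction_shared_peaks = 1,
                 fraction_male_dominant = 0, fraction_female_dominant = 0), g)
  expect_identical(all_shared$peaks_m, all_shared$peaks_f)
  s <- classify_overlap(all_shared$peaks_m, all_shared$peaks_f)$summary
  expect_equal(s$unique_a + s$unique_b, 0L)
  none_shared <- generate_peak_landscape(
    small_config(fraction_shared_peaks = 0,
                 fraction_male_dominant = 0, fraction_female_dominant = 0), g)
  s0 <- classify_overlap(none_shared$peaks_m, none_shared$peaks_f)$summary
  expect_equal(s0$common_a + s0$common_b, 0L)
})

test_that("simulated tracks emit Poisson window counts around planted rates", {
  cfg <- small_config(seed = 7, n_peaks = 1200, fraction_shared_peaks = 1,
                      fraction_male_dominant = 0, fraction_female_dominant = 0)
  g <- generate_annotation(cfg)
  land <- generate_peak_landscape(cfg, g)
  tracks <- simulate_tracks(cfg, g, land$truth)
  win <- summit_window(land$peaks_m, 300)
  counts <- count_in_window(tracks$rxr_m, win)
  expect_equal(length(counts), 1200)
  expect_true(mean(counts) > 47 && mean(counts) < 53)   # lambda0 = 50
  # determinism
  tracks2 <- simulate_tracks(cfg, g, land$truth)
  expect_equal(count_in_window(tracks2$rxr_m, win), counts)
  expect_equal(tracks$rxr_m$library_size, tracks2$rxr_m$library_size)
})

test_that("zero background leaves inter-peak space empty", {
  cfg <- small_config(seed = 3, background_rate = 0)
  g <- generate_annotation(cfg)
  land <- generate_peak_landscape(cfg, g)
  tracks <- simulate_tracks(cfg, g, land$truth)
  # total reads = reads in summit windows (rxr track has no gene-body reads)
  win <- summit_window(land$truth$peaks, 300)
  win$chrom <- land$truth$peaks$chrom
  expect_equal(sum(count_in_window(tracks$rxr_f, win)),
               sum(as.numeric(S4Vectors::runValue(tracks$rxr_f$values$chr1) *
                                S4Vectors::runLength(tracks$rxr_f$values$chr1))))
})

test_that("expression matrix carries the planted fold changes", {
  cfg <- small_config(seed = 5, expression_sd = 1e-9)
  g <- generate_annotation(cfg)
  truth <- generate_peak_landscape(cfg, g)$truth
  expr <- simulate_expression(cfg, truth)
  expect_equal(names(expr), c("gene_id", "M_1", "M_2", "M_3", "F_1", "F_2", "F_3"))
  fc <- rowMeans(expr[, 2:4]) / rowMeans(expr[, 5:7])
  dom_m <- truth$genes$true_class == "male_dominant"
  dom_f <- truth$genes$true_class == "female_dominant"
  # noise-free limit: measured FC equals the planted multiplier exactly
  expect_equal(fc[dom_m], rep(4, sum(dom_m)), tolerance = 1e-6)
  expect_equal(fc[dom_f], rep(1 / 4, sum(dom_f)), tolerance = 1e-6)
  expect_equal(fc[truth$genes$true_class == "none"],
               rep(1, sum(truth$genes$true_class == "none")), tolerance = 1e-6)
  expect_identical(expr, simulate_expression(cfg, truth))
})

test_that("fixture bundles are complete, reproducible and round-trip", {
  cfg <- small_config(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(cfg, d1)
  m2 <- write_fixture_bundle(cfg, d2)
  expect_equal(nrow(m1), 10)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  expect_equal(m1$md5, m2$md5)   # same seed -> identical checksums
  # read back through the i/o layer
  g <- generate_annotation(cfg)
  land <- generate_peak_landscape(cfg, g)
  pk_back <- read_peaks(file.path(d1, "rxr_peaks_male.narrowPeak"))
  expect_equal(pk_back$start, land$peaks_m$start)
  expect_equal(pk_back$summit, land$peaks_m$summit)
  expect_equal(pk_back$height, land$peaks_m$height)
  g_back <- read_gene_models(file.path(d1, "genes.refFlat"))
  expect_equal(g_back$tss, g$tss)
  expect_equal(g_back$exon_starts, g$exon_starts)
  tracks <- simulate_tracks(cfg, g, land$truth)
  t_back <- read_coverage(file.path(d1, "rxr_coverage_male.bedGraph"))
  win <- summit_window(land$peaks_m, 300)
  expect_equal(count_in_window(t_back, win), count_in_window(tracks$rxr_m, win))
  expr_back <- read_expression(file.path(d1, "expression.tsv"))
  expect_equal(expr_back$M_1, simulate_expression(cfg, land$truth)$M_1)
})
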