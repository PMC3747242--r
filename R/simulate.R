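#' Simulation configuration
#'
#' Parameters of the synthetic paired-ChIP-seq study. Defaults describe a
#' compact but realistic two-condition liver-like design: a 10 Mb genome (2
#' chromosomes x 5 Mb) carrying 200 genes and 2,000 binding sites, of which
#' 80% are shared between the sexes; 10% of genes are planted male-dominant
#' and 10% female-dominant, each with a 4-fold occupancy and expression
#' effect over a baseline of 50 reads per 300-bp summit window.
#'
#' @param seed integer master seed; every stage derives its own substream
#'   from it, so outputs are bit-reproducible and stages can be regenerated
#'   independently.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param n_genes number of gene models (non-overlapping, strand
#'   alternating, 2-5 exons each).
#' @param n_peaks total binding sites across the two condition peak sets.
#' @param fraction_shared_peaks fraction of non-planted peaks present at
#'   identical coordinates in both sets; the rest split evenly into
#'   male-only and female-only peaks.
#' @param fraction_male_dominant,fraction_female_dominant fraction of genes
#'   planted as dominant in each direction (each gets one peak within
#'   +/-10 kb of its TSS with a `effect_multiplier`-fold rate difference, a
#'   matching Pol2 effect, and a matching expression fold change).
#' @param baseline_rate expected reads per 300-bp window for a null peak.
#' @param effect_multiplier rate ratio planted for the dominant direction.
#' @param pol2_baseline expected gene-body Pol2 reads for a null gene.
#' @param background_rate background reads per bp scattered uniformly over
#'   each chromosome (per track).
#' @param expression_sd replicate noise SD on the log2 expression scale.
#' @param n_replicates expression replicates per condition (>= 2).
#' @param library_size_m,library_size_f optional library-size normalizers;
#'   `NULL` uses each simulated track's actual read total.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2, chromosome_length = 5e6,
                              n_genes = 200, n_peaks = 2000,
                              fraction_shared_peaks = 0.8,
                              fraction_male_dominant = 0.1,
                              fraction_female_dominant = 0.1,
                              baseline_rate = 50, effect_multiplier = 4,
                              pol2_baseline = 100, background_rate = 1e-4,
                              expression_sd = 0.2, n_replicates = 3,
                              library_size_m = NULL, library_size_f = NULL) {
  if (fraction_male_dominant + fraction_female_dominant > 1) {
    stop_dimorph("simulation_config: dominant fractions sum to > 1")
  }
  frs <- c(fraction_shared_peaks, fraction_male_dominant, fraction_female_dominant)
  if (any(frs < 0 | frs > 1)) stop_dimorph("simulation_config: fractions must be in [0,1]")
  if (baseline_rate <= 0 || pol2_baseline <= 0) {
    stop_dimorph("simulation_config: rates must be > 0")
  }
  if (effect_multiplier <= 1) stop_dimorph("simulation_config: effect_multiplier must be > 1")
  if (n_replicates < 2) stop_dimorph("simulation_config: n_replicates must be >= 2")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_dimorph("simulation_config: seed must be a single integer")
  }
  structure(list(
    seed = as.integer(seed), n_chromosomes = n_chromosomes,
    chromosome_length = chromosome_length, n_genes = n_genes,
    n_peaks = n_peaks, fraction_shared_peaks = fraction_shared_peaks,
    fraction_male_dominant = fraction_male_dominant,
    fraction_female_dominant = fraction_female_dominant,
    baseline_rate = baseline_rate, effect_multiplier = effect_multiplier,
    pol2_baseline = pol2_baseline, background_rate = background_rate,
    expression_sd = expression_sd, n_replicates = n_replicates,
    library_size_m = library_size_m, library_size_f = library_size_f
  ), class = "simulation_config")
}

# internal: derived per-stage substream seed, kept within 32-bit range
stage_seed <- function(config, stage) {
  offsets <- c(annotation = 101L, landscape = 211L, tracks = 307L,
               expression = 401L)
  as.integer((as.numeric(config$seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# internal: run code under a stage's RNG substream without disturbing the
# caller's RNG state
with_stage_seed <- function(config, stage, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(config, stage))
  force(code)
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping gene models with alternating strands on
#' the configured genome, one per fixed-size slot so packing is guaranteed;
#' each gene is 2-10 kb long with 2-5 exons. Deterministic given the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return Gene-model tibble (see [read_gene_models()]).
#' @export
generate_annotation <- function(config) {
  n_chrom <- config$n_chromosomes
  clen <- config$chromosome_length
  n_genes <- config$n_genes
  per_chrom <- ceiling(n_genes / n_chrom)
  slot <- floor(clen / per_chrom)
  max_len <- 10000
  margin <- 11000   # keeps +/-10 kb TSS windows inside the slot
  if (slot < max_len + 2 * margin) {
    stop_dimorph(paste0("generate_annotation: cannot pack %d genes into ",
                        "%d x %g bp (slot %d bp too small)"),
                 n_genes, n_chrom, clen, slot)
  }
  with_stage_seed(config, "annotation", {
    rows <- map(seq_len(n_genes), function(i) {
      chrom_i <- ((i - 1) %/% per_chrom) + 1
      slot_i <- (i - 1) %% per_chrom
      len <- sample(2000:max_len, 1)
      start <- as.integer(slot_i * slot + margin +
                            sample.int(slot - len - 2 * margin, 1))
      end <- as.integer(start + len)
      strand <- if (i %% 2 == 1) "+" else "-"
      n_ex <- sample(2:5, 1)
      # alternate exon/intron segments spanning [start, end)
      cuts <- sort(sample(seq(start + 1, end - 1), 2 * n_ex - 2))
      bounds <- c(start, cuts, end)
      ex_s <- bounds[seq(1, 2 * n_ex - 1, by = 2)]
      ex_e <- bounds[seq(2, 2 * n_ex, by = 2)]
      tibble(gene_id = sprintf("gene%03d", i),
             symbol = sprintf("Gene%03d", i),
             chrom = paste0("chr", chrom_i), strand = strand,
             tx_start = start, tx_end = end,
             tss = if (strand == "+") start else end - 1L,
             tes = if (strand == "+") end - 1L else start,
             exon_starts = list(as.integer(ex_s)),
             exon_ends = list(as.integer(ex_e)))
    })
    bind_rows(rows)
  })
}

#' Generate condition peak sets with planted dimorphic structure
#'
#' Builds the male and female binding-site landscapes and the ground-truth
#' table. Dominant genes (per the config fractions) each receive one
#' *planted* peak within +/-5 kb of their TSS with window-read rates
#' (`baseline_rate * effect_multiplier`, `baseline_rate`) oriented by
#' class; the remaining peaks are split into shared peaks (identical
#' coordinates in both sets, equal baseline rates) and unique peaks
#' (present in one set, baseline rate there, zero in the other). All peaks
#' are 300 bp wide with the summit at the interval midpoint, and summits
#' sit on a 1-kb grid so counting windows never overlap.
#'
#' @param config a [simulation_config()].
#' @param genes output of [generate_annotation()].
#' @return List with elements `peaks_m`, `peaks_f` (peak tibbles) and
#'   `truth`, a list of class `truth_table` with `genes` (per-gene
#'   `true_class`, planted peak, rates, expression fold change) and `peaks`
#'   (per-peak planted rates for both conditions).
#' @export
generate_peak_landscape <- function(config, genes) {
  check_genes(genes)
  lam0 <- config$baseline_rate
  mult <- config$effect_multiplier
  n_m <- round(config$fraction_male_dominant * nrow(genes))
  n_f <- round(config$fraction_female_dominant * nrow(genes))
  with_stage_seed(config, "landscape", {
    cls <- rep("none", nrow(genes))
    dom_idx <- sample.int(nrow(genes), n_m + n_f)
    cls[dom_idx[seq_len(n_m)]] <- "male_dominant"
    if (n_f > 0) cls[dom_idx[n_m + seq_len(n_f)]] <- "female_dominant"

    # 1-kb summit grid guarantees non-overlapping 300-bp windows
    grid <- tidyr::expand_grid(
      chrom = paste0("chr", seq_len(config$n_chromosomes)),
      summit = seq(500, config$chromosome_length - 500, by = 1000)
    )
    grid_key <- paste(grid$chrom, grid$summit)
    used <- rep(FALSE, nrow(grid))

    # planted peaks: nearest free grid point to TSS + U(-5kb, 5kb)
    planted <- map(which(cls != "none"), function(i) {
      target <- genes$tss[i] + sample(-5000:5000, 1)
      cand <- which(grid$chrom == genes$chrom[i] & !used &
                      abs(grid$summit - target) <= 5000 &
                      abs(grid$summit - genes$tss[i]) <= 9000)
      if (length(cand) == 0) {
        cand <- which(grid$chrom == genes$chrom[i] & !used &
                        abs(grid$summit - genes$tss[i]) <= 9000)
      }
      j <- cand[which.min(abs(grid$summit[cand] - target))]
      used[j] <<- TRUE
      male <- cls[i] == "male_dominant"
      tibble(name = paste0("peak_", genes$gene_id[i]),
             chrom = grid$chrom[j], summit = grid$summit[j],
             rate_m = if (male) lam0 * mult else lam0,
             rate_f = if (male) lam0 else lam0 * mult,
             set = "planted", gene_id = genes$gene_id[i])
    }) |> bind_rows()

    n_rest <- config$n_peaks - nrow(planted)
    if (n_rest < 0) stop_dimorph("generate_peak_landscape: n_peaks < number of dominant genes")
    n_shared <- round(config$fraction_shared_peaks * n_rest)
    n_uniq_m <- (n_rest - n_shared) %/% 2
    n_uniq_f <- n_rest - n_shared - n_uniq_m
    free <- which(!used)
    if (length(free) < n_rest) stop_dimorph("generate_peak_landscape: summit grid exhausted")
    picks <- sample(free, n_rest)
    kind <- rep(c("shared", "unique_m", "unique_f"), c(n_shared, n_uniq_m, n_uniq_f))
    rest <- tibble(
      name = c(sprintf("shared_%04d", seq_len(n_shared)),
               sprintf("m_only_%04d", seq_len(n_uniq_m)),
               sprintf("f_only_%04d", seq_len(n_uniq_f))),
      chrom = grid$chrom[picks], summit = grid$summit[picks],
      rate_m = if_else(kind == "unique_f", 0, lam0),
      rate_f = if_else(kind == "unique_m", 0, lam0),
      set = kind, gene_id = NA_character_
    )
    all_peaks <- bind_rows(planted, rest) |>
      mutate(summit = as.integer(.data$summit),
             start = .data$summit - 150L, end = .data$summit + 150L,
             score = 0, strand = ".")
    to_peaks <- function(rows, height) {
      rows |>
        mutate(height = height) |>
        select("chrom", "start", "end", "name", "score", "strand",
               "height", "summit") |>
        arrange(.data$chrom, .data$start)
    }
    peaks_m <- all_peaks |> filter(.data$rate_m > 0) |>
      (\(d) to_peaks(d, d$rate_m))()
    peaks_f <- all_peaks |> filter(.data$rate_f > 0) |>
      (\(d) to_peaks(d, d$rate_f))()

    truth_genes <- tibble(
      gene_id = genes$gene_id,
      true_class = cls,
      planted_peak = if_else(cls == "none", NA_character_,
                             paste0("peak_", genes$gene_id)),
      rate_m = case_when(cls == "male_dominant" ~ lam0 * mult,
                         cls == "female_dominant" ~ lam0,
                         .default = NA_real_),
      rate_f = case_when(cls == "female_dominant" ~ lam0 * mult,
                         cls == "male_dominant" ~ lam0,
                         .default = NA_real_),
      pol2_rate_m = case_when(cls == "male_dominant" ~ config$pol2_baseline * mult,
                              .default = config$pol2_baseline),
      pol2_rate_f = case_when(cls == "female_dominant" ~ config$pol2_baseline * mult,
                              .default = config$pol2_baseline),
      expression_log2fc = case_when(cls == "male_dominant" ~ log2(mult),
                                    cls == "female_dominant" ~ -log2(mult),
                                    .default = 0)
    )
    truth <- structure(list(genes = truth_genes,
                            peaks = select(all_peaks, "name", "chrom", "summit",
                                           "rate_m", "rate_f", "set", "gene_id")),
                       class = "truth_table")
    list(peaks_m = peaks_m, peaks_f = peaks_f, truth = truth)
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> ", nrow(x$genes), " genes (",
      sum(x$genes$true_class == "male_dominant"), " male-dominant, ",
      sum(x$genes$true_class == "female_dominant"), " female-dominant), ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

# internal: scatter n reads uniformly over [lo, hi) on one chromosome
scatter_reads <- function(chrom, lo, hi, n) {
  if (n == 0) return(tibble(chrom = character(), pos = integer()))
  tibble(chrom = chrom, pos = lo + sample.int(hi - lo, n, replace = TRUE) - 1L)
}

#' Simulate condition read tracks
#'
#' Emits point-read coverage (one count at each read's 5' position) for four
#' samples: the binding-factor ChIP in each condition (reads Poisson around
#' each peak's planted window rate, uniform within the 300-bp summit
#' window) and the Pol2 ChIP in each condition (gene-body reads Poisson
#' around the planted Pol2 rate, uniform over the TSS-TES span). A uniform
#' background at `background_rate` reads/bp is added to every track.
#' Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param genes output of [generate_annotation()].
#' @param truth the `truth_table` from [generate_peak_landscape()].
#' @return List of four [coverage_track]s: `rxr_m`, `rxr_f`, `pol2_m`,
#'   `pol2_f`.
#' @export
simulate_tracks <- function(config, genes, truth) {
  stopifnot(inherits(truth, "truth_table"))
  chrom_lengths <- setNames(rep(config$chromosome_length, config$n_chromosomes),
                            paste0("chr", seq_len(config$n_chromosomes)))
  with_stage_seed(config, "tracks", {
    peak_reads <- function(rates) {
      counts <- rpois(nrow(truth$peaks), rates)
      bind_rows(pmap(list(truth$peaks$chrom, truth$peaks$summit, counts),
                     function(ch, s, n) scatter_reads(ch, s - 150L, s + 150L, n)))
    }
    gene_reads <- function(rates) {
      lo <- pmin(genes$tss, genes$tes)
      hi <- pmax(genes$tss, genes$tes) + 1L
      counts <- rpois(nrow(genes), rates)
      bind_rows(pmap(list(genes$chrom, lo, hi, counts), scatter_reads))
    }
    background <- function() {
      bind_rows(map(names(chrom_lengths), function(ch) {
        n <- rpois(1, config$background_rate * chrom_lengths[[ch]])
        scatter_reads(ch, 0L, as.integer(chrom_lengths[[ch]]), n)
      }))
    }
    tg <- truth$genes
    mk <- function(reads, override) {
      track_from_reads(reads, chrom_lengths,
                       library_size = override %||% max(nrow(reads), 1))
    }
    list(
      rxr_m = mk(bind_rows(peak_reads(truth$peaks$rate_m), background()),
                 config$library_size_m),
      rxr_f = mk(bind_rows(peak_reads(truth$peaks$rate_f), background()),
                 config$library_size_f),
      pol2_m = mk(bind_rows(gene_reads(tg$pol2_rate_m), background()),
                  config$library_size_m),
      pol2_f = mk(bind_rows(gene_reads(tg$pol2_rate_f), background()),
                  config$library_size_f)
    )
  })
}

#' Simulate an expression matrix with planted fold changes
#'
#' Each gene gets a baseline log2 intensity drawn uniformly in [6, 12];
#' dominant genes are shifted by half the planted log2 fold change up in
#' the matching condition and down in the other, and every replicate adds
#' N(0, `expression_sd`^2) noise on the log2 scale. Values are returned on
#' the linear scale. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth_table` from [generate_peak_landscape()].
#' @return Expression tibble: `gene_id`, then `M_1..M_r`, `F_1..F_r`.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(truth, "truth_table"))
  tg <- truth$genes
  r <- config$n_replicates
  with_stage_seed(config, "expression", {
    base <- runif(nrow(tg), 6, 12)
    mu_m <- base + tg$expression_log2fc / 2
    mu_f <- base - tg$expression_log2fc / 2
    out <- tibble(gene_id = tg$gene_id)
    for (j in seq_len(r)) {
      out[[paste0("M_", j)]] <- 2^(mu_m + rnorm(nrow(tg), 0, config$expression_sd))
    }
    for (j in seq_len(r)) {
      out[[paste0("F_", j)]] <- 2^(mu_f + rnorm(nrow(tg), 0, config$expression_sd))
    }
    out
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Runs all generator stages and writes the standard-format files the
#' pipeline consumes: two narrowPeak peak sets, four bedGraph tracks
#' (binding factor and Pol2, each per condition), a refFlat gene table, the
#' expression TSV, the gene-level truth TSV and a YAML copy of the config —
#' ten files plus a manifest with MD5 checksums. Re-running with the same
#' seed reproduces identical files.
#'
#' @param config a [simulation_config()].
#' @param output_dir directory to create/populate.
#' @return Tibble manifest (`file`, `path`, `md5`), invisibly; also written
#'   as `manifest.tsv`.
#' @export
write_fixture_bundle <- function(config, output_dir) {
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE)
  if (!ok || file.access(output_dir, 2) != 0) {
    stop_dimorph("write_fixture_bundle: cannot write to %s", output_dir)
  }
  genes <- generate_annotation(config)
  land <- generate_peak_landscape(config, genes)
  tracks <- simulate_tracks(config, genes, land$truth)
  expr <- simulate_expression(config, land$truth)

  p <- function(f) file.path(output_dir, f)
  write_peaks(land$peaks_m, p("rxr_peaks_male.narrowPeak"))
  write_peaks(land$peaks_f, p("rxr_peaks_female.narrowPeak"))
  write_coverage(tracks$rxr_m, p("rxr_coverage_male.bedGraph"), "rxr_m")
  write_coverage(tracks$rxr_f, p("rxr_coverage_female.bedGraph"), "rxr_f")
  write_coverage(tracks$pol2_m, p("pol2_coverage_male.bedGraph"), "pol2_m")
  write_coverage(tracks$pol2_f, p("pol2_coverage_female.bedGraph"), "pol2_f")
  write_gene_models(genes, p("genes.refFlat"))
  readr::write_tsv(expr, p("expression.tsv"))
  readr::write_tsv(land$truth$genes, p("truth_genes.tsv"))
  cfg <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(cfg, p("config.yaml"))

  files <- c("rxr_peaks_male.narrowPeak", "rxr_peaks_female.narrowPeak",
             "rxr_coverage_male.bedGraph", "rxr_coverage_female.bedGraph",
             "pol2_coverage_male.bedGraph", "pol2_coverage_female.bedGraph",
             "genes.refFlat", "expression.tsv", "truth_genes.tsv", "config.yaml")
  manifest <- tibble(file = files, path = file.path(output_dir, files),
                     md5 = unname(tools::md5sum(file.path(output_dir, files))))
  readr::write_tsv(manifest, p("manifest.tsv"))
  invisible(manifest)
}
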