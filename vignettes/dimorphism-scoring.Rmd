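---
title: "Scoring sexually dimorphic occupancy from paired ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sexually dimorphic occupancy from paired ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sex differences in gene regulation are widespread in mammalian liver, where
nuclear-receptor signalling and growth-hormone secretion patterns diverge
between males and females. When a transcription factor is ChIP-sequenced
once per sex — the common design when animals are pooled and replicates are
spent on conditions rather than repeats — the question "is this binding
site stronger in one sex?" reduces to comparing two read counts. This
package implements that comparison, the downstream gene-level calls, and a
synthetic study generator with planted ground truth so that every stage can
be validated without external data.

## The score

For each called peak, reads from both condition samples are counted in a
300-bp window centered on the peak summit (`summit_window()`, clipped at
position 0). Window counts are modelled as Poisson; a p-value for the
between-condition difference is transformed to the signed score

$$ \mathrm{score} = \pm \log_2(-10 \log_{10} p), $$

with positive sign when the male sample has the stronger library-normalized
count. The double log makes the score compact: ±6 corresponds to
$p = 10^{-6.4} \approx 4\times10^{-7}$, ±3 to $p = 10^{-0.8} \approx 0.16$.
A score magnitude above 6 is called significantly dimorphic; magnitudes in
$[3, 6]$ are the Medium stratum and below 3 Low (both stratum boundaries
fall in Medium; High is strict, since only scores *greater than* 6 count as
significant).

The same machinery yields the Pol2 gene score: RNA polymerase II reads are
summed over the genomic span between the transcription start and end sites
(`score_genes_pol2()`; strand-agnostic, since read counting is), and the
identical test and transform are applied. A strong Pol2 score marks a gene
as differentially transcribed, complementary evidence to differential
binding.

## The two-sample Poisson test

The package ships two variants, selectable via
`score_config(test_method = ...)`:

* **`conditional_binomial`** (default). For counts $k_m, k_f$ with library
  sizes $N_m, N_f$, conditioning on the total $n = k_m + k_f$ makes the
  stronger side's count Binomial$(n, p_0)$ under the equal-rate null, with
  $p_0$ that side's share $N/(N_m+N_f)$. The reported p-value is the
  one-sided upper tail in the direction of the observed excess. This is
  the classical exact test for a ratio of Poisson rates, and it is
  calibrated: under the null, $P(p < \alpha) \le \alpha$ per direction.
* **`poisson_tail`**. The smaller normalized count, rescaled to the
  stronger side's library and floored at `lambda_min`, is treated as a
  known Poisson rate $\lambda$, and $p = P(X \ge k_{\max})$,
  $X \sim \mathrm{Poisson}(\lambda)$. This plug-in form is simpler but
  anticonservative at moderate rates, because it ignores the sampling
  noise in the reference count: the minimum of two equal-rate draws
  systematically underestimates the common rate, inflating the apparent
  excess of the larger draw.

We made the conditional binomial the default after checking both variants'
null behaviour exactly (summing the joint Poisson pmf over count pairs):
at window rates around 50 the plug-in tail produces orders of magnitude
more false high scores than its nominal level, while the conditional test
stays within it. The package's null-calibration test — $10^5$ equal-rate
peak pairs at rate 50 must yield at most one $|\mathrm{score}| > 6$ —
passes with the default and is the property a practitioner should care
about. Both variants agree with independent term-by-term tail summation to
better than $10^{-12}$ relative error over all count pairs up to 200
(checked in the acceptance suite).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window` | 300 bp | summit-centered counting window (even) |
| `high_threshold` | 6 | score magnitude for a High/significant call ($p < 10^{-6.4}$) |
| `medium_threshold` | 3 | lower edge of the Medium stratum ($p \le 10^{-0.8}$) |
| `test_method` | conditional_binomial | Poisson-difference test variant |
| `p_floor` | 1e-300 | clamp keeping the score finite |
| `lambda_min` | 1 | rate floor so a $(k, 0)$ pair has finite p (poisson_tail) |
| `up`, `down` | 10,000 bp | strand-oriented TSS window for peak-to-gene assignment, boundaries inclusive |
| `tss_window`, `tes_window` | 500 bp | feature-annotation windows |
| `fc_cutoff`, `p_cutoff` | 1.5, 0.1 | expression screen |
| `max_per_position` | 2 | PCR-duplicate rule: reads kept per (position, strand) |

## Gene-level calls

Peaks are assigned to genes whose TSS lies within the ±10 kb window
(`assign_genes()`, mode `"tss_window"`; a `nearest_tss` mode exists for
genome-wide summaries where every peak should map somewhere). A gene is
called **male-dominant** when at least one assigned peak scores above the
high threshold *and* its Pol2 score does too; **female-dominant** mirrors
this below the negative threshold. The conjunction is the point: a strong
binding difference over a transcriptionally inert gene, or a transcription
difference without a binding difference, is not called. Directions cannot
conflict because both criteria carry the same sign.

The optional third layer intersects these calls with a microarray-style
expression screen (`differential_expression()`): equal-variance Student
t-test on log2 intensities (the scale on which array noise is roughly
homoscedastic; Welch available via `var_equal = FALSE`), fold change
computed on linear-scale means as larger/smaller, pass when FC > 1.5 and
raw p < 0.1. No multiple-testing correction is applied — the screen is a
filter stacked on two much stricter chromatin criteria, not a discovery
procedure in its own right. Genes with several probes collapse to the
brightest probe; a gene absent from the expression table simply fails the
RNA criterion.

## What the generator emulates — and what it does not

`simulation_config()` defaults define the study conditions used throughout
the tests: 2 chromosomes × 5 Mb, 200 genes (one per 50-kb slot,
alternating strands, 2–5 exons), 2,000 peaks of which 80% are shared
between conditions, 10% of genes planted male-dominant and 10%
female-dominant, baseline 50 reads per 300-bp window, 4-fold planted
effects in binding, Pol2 (baseline 100 gene-body reads) and expression
(log2 FC = 2, replicate SD 0.2, 3 replicates per condition), and a uniform
background of 1e-4 reads/bp. The shared fraction mirrors the 75–80%
common-peak proportion typical of male/female comparisons of the same
factor; the 4-fold effect and rate 50 are the regime in which the score is
decisively powered (a 200-vs-50 pair scores far above 6), which is what a
recovery test should exercise.

Tracks are **point-read**: each simulated read contributes 1 at its 5'
position, so a window sum *is* a read count and window counts are exact
Poisson draws — the scoring model's assumptions hold by construction.
Peak summits sit on a 1-kb grid, so 300-bp windows never overlap and
planted rates are not confounded. A single master seed derives per-stage
substreams (annotation, landscape, tracks, expression), making every
output bit-reproducible and each stage independently regenerable.

Deliberately not emulated: fragment-length structure and read extension,
GC and mappability bias, copy-number variation, overdispersion beyond
Poisson, correlated peaks, and annotation complexity (overlapping genes,
alternative TSSs). Passing the recovery tests therefore demonstrates that
the pipeline's logic and statistics are correct under the stated model —
not that real ChIP-seq noise is fully captured. On real data the Poisson
assumption is the same one the scoring method itself makes, so the
generator is the matched test bed for it.

## Numerical choices and edge cases

* The score clamps to 0 when $-10\log_{10} p \le 1$ (p near 1) or when the
  normalized counts tie, avoiding the logarithm of a non-positive number;
  only clearly non-significant comparisons are affected.
* p-values are floored at `p_floor = 1e-300` so scores stay finite; a
  `(k, 0)` pair under `poisson_tail` uses `lambda_min = 1`.
* `(0, 0)` counts give p = 1, score 0; zero-coverage genes likewise.
* Coordinates are 0-based half-open throughout (wiggle's 1-based
  declarations converted on read); adjacent intervals share no bases, so
  `[100,200)` vs `[200,300)` is *unique*, not common.
* Peak height strata are right-open with an overflow bin; score strata put
  both boundaries (3 and 6) in Medium, so "High" is strictly > 6.
* `nearest_tss` ties break toward the lexicographically smallest gene id;
  the ±10 kb window is inclusive at exactly 10 kb and oriented by gene
  strand.
* The TES annotation window defaults to ±500 bp, mirroring the TSS window,
  for lack of a principled asymmetric choice.
* Zero-variance, equal-mean expression rows get t = 0, p = 1; zero
  variance with unequal means gets p = 0 (perfect separation).

## Problem sizes

Unit tests run compact studies (1 chromosome × 2 Mb, 40 genes, 300–1,200
peaks); the acceptance suite and `scripts/acceptance.R` run the default
200-gene / 2,000-peak study, a $10^5$-pair null calibration, and the full
$201 \times 201$ count-pair oracle comparison. These sizes were chosen so
the whole suite completes in about a minute while every statistical claim
is still exercised at meaningful scale.

## Limitations

* No replicate-aware dispersion modelling: the method compares single
  pooled samples per condition, which is its intended (and historically
  common) design. With replicates, a negative-binomial framework (DESeq2,
  edgeR) is the right tool instead.
* No multiple-testing correction on peak or gene scores; the ±6 threshold
  is deliberately extreme ($4\times10^{-7}$), which controls the
  genome-wide false-positive count at typical peak-set sizes, but users
  scanning much larger sets should tighten it.
* Library-size normalization uses total mapped reads; composition effects
  (one sex binding globally more) are not corrected.
* Peak calling is upstream: the package consumes called peaks and does not
  re-evaluate their support.
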