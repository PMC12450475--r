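---
title: "Modeling transcription loss from accumulating transcription-blocking lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transcription loss from accumulating transcription-blocking lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txstress)
library(dplyr)
```

## The model

Bulky DNA lesions on the transcribed strand of a gene arrest elongating RNA
polymerase II; when they are not repaired they permanently silence that
allele's output. `txstress` implements a quantitative framework linking the
random accumulation of such transcription-blocking lesions (TBLs) to
genome-wide transcription loss.

The model's assumptions are deliberately minimal:

1. lesions accumulate uniformly at random over the diploid double-stranded
   genome, at a constant rate over time;
2. each gene has two alleles contributing equally to its transcription;
3. a lesion on the transcribed strand of an allele silences that allele;
   a lesion on the untranscribed strand (or intergenic DNA) has no effect.

With gene lengths $l_i$, haploid genome length $L$, and nascent-expression
weights $\alpha_i$ normalized to $\sum_i \alpha_i = 1$, a single uniformly
placed lesion hits the transcribed strand of one allele of gene $i$ with
probability

$$q_i = \frac{l_i}{4L},$$

the factor 4 counting two alleles times two strands. After $M$ independent
lesions the expected fraction of transcription lost is

$$E[\omega_M] \;=\; \sum_i \alpha_i \left(1 - (1 - q_i)^M\right),$$

which `expected_loss()` evaluates with the numerically stable form
$1-(1-q)^M = -\mathrm{expm1}(M\,\mathrm{log1p}(-q))$. The formula makes the
framework's central biological point quantitative: *long genes are larger
targets*, so transcription loss is gene-length-weighted, and expression-rich
long genes dominate the early decline. As $M$ grows the curve saturates —
new lesions increasingly strike already-silenced alleles.

Two conversions anchor $M$ to experiment. UV-C exposure induces about 0.55
TBLs per 100 kb per J/m² (`uv_dose_to_density()`; the factor is an
approximate literature value and stays configurable), and a density per
100 kb converts to a genome-wide count via $M = \mathrm{round}(d \cdot
L/10^5)$ (`density_to_count()`). Density is defined against the *haploid*
length $L$ — that convention, not $4L$, reproduces the published
genome-wide totals (0.55/100 kb ↔ 17,600 on a 3.2 Gb genome). For aging
tissue, $M = r\,(t - t_0)$ with $r$ the daily rate of unrepaired lesions
(`age_to_count()`); lesion counts are treated as integers (events), with
half-away-from-zero rounding since no convention is inherent in the data.

```{r}
density_to_count(uv_dose_to_density(1), 3.2e9)
expected_loss(simulate_gene_catalog(2000, profile = "human", seed = 1),
              c(0, 17600, 105600))
```

## The Monte-Carlo oracle

`simulate_lesions()` is a brute-force check on the closed form: it places
$M$ lesions by sampling, per lesion, a category among {gene $\times$ allele
$\times$ transcribed strand} (probability $q_i$ each) or "anywhere else",
then scores an allele silenced iff it took at least one transcribed-strand
hit. Sampling categories rather than base-pair coordinates is exactly
equivalent for this statistic under the uniformity assumption and orders of
magnitude cheaper. The simulator is the package's *validation* path — the
tests require the Monte-Carlo mean to sit within three standard errors of
the closed form on random catalogs — and `simulate_lesion_trajectory()`
extends it to cumulative aging trajectories in which lesions persist.
Multiple hits on one allele are allowed (they change nothing), matching the
independence assumption. The catalog constraint $\sum_i l_i \le L$
guarantees the category probabilities stay below one.

## Gene catalogs

`read_gene_annotation()` consumes GTF (1-based, inclusive) or BED (0-based,
half-open) and stores 0-based half-open coordinates internally; both
dialects of the same intervals give identical catalogs. Gene length is the
genomic span of the gene's longest transcript, introns included; span ties
are broken by the lexicographically smallest transcript id (the tie-break
is this package's choice — the longest-transcript rule itself does not
determine one). `filter_genes()` applies the inclusion rules used
throughout: genes shorter than 5 kb are excluded, optionally genes longer
than 750 kb (a sensitivity filter against long, highly expressed genes),
and optionally non-expressed genes (0 reads/RPM). `build_catalog()`
normalizes whatever expression unit the input provides into weights —
$\alpha$ is scale-invariant, so reads and RPM give the same catalog.

## Rate calibration and repair arithmetic

`calibrate_rate()` inverts the model at one time point: since $E[\omega_M]$
is strictly monotone in $M$, the integer $M^\*$ minimizing the distance to
the observed loss is found by bracket-doubling plus integer bisection
(tolerance $10^{-6}$ on expected loss, or adjacent-integer bracketing,
whichever first), and $r = M^\*/\Delta t$. Two conventions cover the two
shapes of longitudinal data:

* **first-point calibration** (repair-deficient series, whose first
  measurement already shows loss): accumulation counted from birth
  ($t_0 = 0$); later points validate the fit;
* **last-point calibration** (wildtype-style series whose first point shows
  no loss): $t_0$ defaults to the first measured age, and the fit predicts
  the earlier point. Calibrating on the later, larger signal avoids
  underestimating slow damage rates.

Validation errors follow the magnitude conventions of the field's error
tables: absolute error in percentage points, relative error as a percentage
of the measured loss, both also expressible in SEM multiples
(`dose_error_table()`). With replicate catalogs (one per sequenced animal)
the rate is fitted per catalog and reported as mean ± SD across catalogs
only; per-animal imaging variability is not propagated into that SD.

`repair_capacity()` and `project_residual_rate()` implement the comparative
arithmetic between genotype rates (daily difference, percent retained
capacity, percent persisting/repaired, and rate projections under partial
residual repair activity).

## Dose-response

`eu_to_loss()` converts normalized EU (5-ethynyluridine) intensities to
transcription loss as $100\% - \text{intensity}$, pooling replicate
experiments after each is normalized to its own untreated control
(`normalize_eu()`). `fit_dose_response()` fits loss against lesion density
by ordinary least squares with a raw polynomial design, degree 1 for the
near-linear low-dose regime and degree 3 for the plateau; the cubic's
coefficients are validated by properties (exact interpolation of cubics,
nested-model RSS dominance) rather than reference values, since no
published coefficients exist to compare against. `per_tbl_slope()` reports
the low-dose loss per unit density, which the tests tie to the analytic
linearization $\sum_i \alpha_i q_i \cdot L/10^5$ per TBL per 100 kb.

## The tilt statistic

`body_slope()` fits an OLS line to binned gene-body coverage (RPKM versus
0-based bin index, 5′→3′, strand resolved upstream), and
`gene_tilt()`/`cohort_tilt()` report the after-minus-before slope
difference. Negative tilt means coverage decays toward the 3′ end after
damage — polymerases stall at lesions before finishing transcripts. The bin
count defaults to 20 equal-width bins; the published description fixes
neither bin count nor trimming, so these defaults are documented as this
package's choices, not inferred ones. Binning length-normalizes genes, so
tilts are comparable across genes; raw-coordinate slopes are deliberately
not offered.

## Image quantification

`quantify_field()` reproduces the stated microscopy pipeline on two-channel
(EU + DNA) fields: Otsu threshold on the DNA channel with hole filling and
connected-component labeling (`segment_nuclei()`; touching nuclei are not
split — no watershed is promised), nucleolar exclusion, per-nucleus
measurement, and species gates. Nucleoli — bright rRNA foci in the EU
channel, chromatin-poor holes in the DNA channel — are segmented on the EU
channel with a moment-preserving (Tsai) threshold after background
subtraction by grayscale opening (`segment_nucleoli()`). The published
workflow used ImageJ's 'Moments' autothreshold and rolling-ball background;
this package's variant (Tsai's original moment-preservation criterion,
opening with a 25 px disc by default) is validated against constructed
ground truth rather than claimed byte-equivalent to ImageJ. A separability
guard (between-class variance fraction ≥ 0.75) returns an empty mask for
nucleolus-free nuclei instead of thresholding noise.

Gates (`species_profile()`): mouse hepatocytes keep nuclei of 24.4–70 µm²
with circularity > 0.7 — the upper bound removes polyploid nuclei, which
the diploid model does not cover — plus a low-EU gate for Kupffer-like
cells; human fibroblasts use 24.4–250 µm² and circularity > 0.6.
The Kupffer cutoff has no published numeric value (it was drawn per
dataset); the default, 20% of the field's median hepatocyte EU, is an
artifact choice and a config parameter. Circularity is $4\pi A/P^2$ with
the perimeter from the object contour, clipped at 1 for reporting since
discretized perimeters of small disks can underestimate. Per-field
summaries are medians over gate-passing nuclei; cohorts normalize to a
designated reference sample (`normalize_cohort()`).

## The synthetic-data generators

Every input class is generated in code so the full pipeline is testable
offline:

* **Catalogs** (`simulate_gene_catalog()`): log-normal gene spans, median
  25 kb, $\sigma_{\log} = 1.1$, clipped to [5 kb, 750 kb] — chosen once to
  mimic the mammalian gene-span spread; no published distribution exists to
  copy. Expression is log-normal ($\sigma_{\log} = 1.5$); the mouse profile
  multiplies it by $(l/25\,\text{kb})^{0.3}$, emulating the long, highly
  expressed genes characteristic of liver nascent-RNA data. Default genome
  lengths: 2.65 Gb (mouse), 3.2 Gb (human) — the values consistent with the
  published conversion arithmetic. Default catalog sizes in the acceptance
  workflows are 9,000 (mouse-like) and 21,500 (human-like), matching the
  filtered real catalogs.
* **Longitudinal series** (`simulate_loss_series()`): forward model plus
  Gaussian per-animal noise (default SD 2 percentage points, 3 animals —
  the real design's replication).
* **Dose-response** (`simulate_eu_dose_response()`): intensities generated
  from the closed form through the UV conversions, 4 replicate experiments.
* **Coverage profiles** (`simulate_coverage_profiles()`): linear mode with
  exact constructed tilts; truncation mode with geometric per-bin decay
  emulating polymerase stalling.
* **Microscopy fields** (`simulate_fields()`): disk nuclei on a jittered
  grid (so segmentation is never confounded by touching objects), four
  constructed classes (hepatocyte, too-small, dim Kupffer-like, oversized
  polyploid-like), concentric nucleoli at a configured area fraction, and
  Gaussian noise at a configured SNR (default 10). Ground truth, including
  realized pixel counts, travels with the fields.

What passing tests on these fixtures do **not** show: real nascent-RNA
weights are estimated from finite sequencing depth (the generator's weights
are exact); real nuclei are not discs and real illumination is not flat, so
segmentation accuracy on the synthetic fields is an upper bound; and the
constant-rate assumption is itself a modeling idealization — the framework
measures an effective daily rate, not repair kinetics.

## Numerical choices and limitations

* Lesion counts are integers; $r\,\Delta t$ rounds half away from zero.
* Rate bisection terminates at $|E-\text{target}| \le 10^{-6}$ or adjacent
  integers; the calibration-point residual is therefore bounded by the
  expected-loss difference between adjacent $M$.
* Rates print to whole lesions/day; internally they stay unrounded.
* Parameter-recovery checks compare the *mean* fit over three independent
  noisy series with the truth: with per-animal noise of 2 percentage
  points, a single wildtype-scale series (loss signal ~20%) carries
  irreducible sampling error of the same order as the 10% accuracy target,
  so single-draw recovery is not a property any implementation could
  guarantee.
* Problem sizes in the tests and acceptance workflow — 9,000-gene
  catalogs, 10,000 Monte-Carlo replicates, six 12-nucleus fields — were
  chosen as the smallest sizes at which the stochastic tolerances are
  comfortably resolved.
* The framework deliberately omits repair kinetics, replication,
  transcriptional bypass, lesion hotspots and polyploidy; polyploid nuclei
  are excluded at quantification rather than modeled.
* Published rate estimates themselves disagree across sections of the
  source literature (e.g. a wildtype daily burden quoted as ~15 in one
  discussion and 62 in the fitted tables; an 18-week lesion total not
  reconstructible from the quoted rate and any obvious accumulation
  window). The package implements the fitted-table convention ($M = rt$
  from $t_0$) and leaves such discrepancies to the user's judgment.

## Reproducing the headline numbers

`run_demo()` exercises every stage end to end on synthetic data and writes
a deterministic report. `scripts/acceptance.R` (repository root) recomputes
the conversion arithmetic, repair capacities, error-table means, and
rate-recovery results from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
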