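# txstress

Quantitative modeling of genome-wide transcription loss caused by randomly
accumulating transcription-blocking DNA lesions (TBLs).

Persistent bulky DNA lesions on the transcribed strand arrest RNA
polymerase II and silence the damaged allele. Because longer genes are
larger targets, random damage preferentially extinguishes long-gene
transcription — a signature of both UV exposure in repair-deficient cells
and of aging tissue. `txstress` is for researchers who want to turn
measured transcription decline (nascent-RNA EU incorporation, by imaging or
sequencing) into quantitative damage estimates: how many lesions does a
dose correspond to, how many unrepaired lesions accumulate per day, and how
much repair capacity does a mutant retain.

## The model

For a catalog of genes with lengths $l_i$, nascent-expression weights
$\alpha_i$ ($\sum\alpha_i = 1$) and haploid genome length $L$, a uniformly
placed lesion hits the transcribed strand of one allele of gene $i$ with
probability

$$q_i = \frac{l_i}{4L}$$

(two alleles × two strands), and the expected transcription loss after $M$
lesions is

$$E[\omega_M] = \sum_i \alpha_i\left(1-(1-q_i)^M\right).$$

Around this closed form the package provides:

* **gene catalogs** from GTF/BED + count tables (`read_gene_annotation()`,
  `filter_genes()`, `build_catalog()`), with the standard inclusion rules
  (≥ 5 kb, optionally ≤ 750 kb, expressed genes);
* a **Monte-Carlo lesion-placement simulator** on the diploid genome
  (`simulate_lesions()`), the brute-force oracle validating the closed form;
* **conversions** between UV dose, lesion density per 100 kb, genome-wide
  count and age (`uv_dose_to_density()`, `density_to_count()`,
  `age_to_count()`);
* **rate calibration**: fit the daily unrepaired-lesion rate $r$ from one
  time point of a longitudinal loss series and validate on the rest
  (`calibrate_rate()`, `validate_rate()`), plus repair-capacity arithmetic
  between genotypes (`repair_capacity()`, `project_residual_rate()`);
* **dose-response** fitting of EU-derived loss vs lesion density, linear
  and third-order polynomial, with model-vs-data error tables
  (`eu_to_loss()`, `fit_dose_response()`, `dose_error_table()`);
* the gene-body **tilt** statistic for 5′→3′ coverage redistribution after
  damage (`body_slope()`, `gene_tilt()`, `cohort_tilt()`);
* **microscopy quantification** of nucleoplasmic EU intensity with nuclei
  segmentation, nucleolar exclusion and size/circularity/intensity gates
  (`quantify_field()`, `species_profile()`);
* **synthetic-data generators** for every input class
  (`simulate_gene_catalog()`, `simulate_loss_series()`,
  `simulate_eu_dose_response()`, `simulate_coverage_profiles()`,
  `simulate_fields()`), so the whole pipeline runs without downloads.

Functions take data frames and return tibbles; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Calibrate a daily lesion rate from a synthetic longitudinal series on a
mouse-liver-like catalog:

```r
library(txstress)

catalog <- simulate_gene_catalog(9000, profile = "mouse", seed = 1)
loss_curve(catalog, c(0, 17600, 105600))
#> # A tibble: 3 × 6
#>     grid      M expected_loss    sd ci95_lo ci95_hi
#>    <dbl>  <dbl>         <dbl> <dbl>   <dbl>   <dbl>
#> 1      0      0        0          0  0       0
#> 2  17600  17600        0.0994     0  0.0994  0.0994
#> 3 105600 105600        0.375      0  0.375   0.375

series <- simulate_loss_series(catalog, rate = 2315,
                               ages_weeks = c(10, 16, 21),
                               noise_sd = 2, seed = 1)
series
#> # A tibble: 3 × 4
#>   genotype  age_weeks loss_pct sem_pct
#> 1 synthetic        10     46.7   0.622
#> 2 synthetic        16     59.7   1.40
#> 3 synthetic        21     66.7   0.147

fit <- calibrate_rate(catalog, series)
fit
#> <rate_fit> [synthetic] r = 2235 lesions/day (SD 0 across 1 catalog)
#>   calibrated on the first point (10 weeks), t0 = 0 weeks
#>   validation: mean |error| 1.8 pct points, mean relative 2.9%
```

The catalog's expected-loss curve says 17,600 genome-wide lesions (1 J/m²
of UV-C on a human-size genome) cost ~10% of transcription, and 105,600
(6 J/m²) cost ~37%. The series was generated at a true rate of 2,315
lesions/day with 2-percentage-point observation noise; calibrating on the
first time point alone recovers 2,235/day (3.5% off) and predicts the two
held-out time points to within 1.8 percentage points.

Repair-capacity arithmetic between genotype rates:

```r
repair_capacity(1621, 4978)
#> # A tibble: 1 × 4
#>   daily_difference percent_of_reference percent_persisting percent_repaired
#> 1             3357                 67.4               32.6             67.4
```

A genotype accumulating 1,621 lesions/day against a reference of 4,978
still repairs 3,357 lesions daily — 67.4% retained repair capacity.

`run_demo(out_dir, seed)` runs every stage end to end on synthetic data
and writes a deterministic report.

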