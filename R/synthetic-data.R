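#' Simulate a gene catalog with realistic length and expression spread
#'
#' Gene spans are drawn log-normally (default median 25 kb, sdlog 1.1,
#' mimicking the mammalian gene-span distribution) and clipped to the
#' catalog inclusion window (5 kb to 750 kb by default, the same rules
#' applied to real annotations). Expression is heavy-tailed log-normal;
#' for the mouse profile it is multiplied by `(length/25 kb)^boost`
#' (default boost 0.3), emulating the long, relatively highly expressed
#' genes characteristic of liver nascent-RNA data. Catalog sizes of about
#' 9,000 (mouse-like) and 21,500 (human-like) match the filtered real
#' catalogs.
#'
#' @param n_genes Number of genes (after clipping; all draws are kept and
#'   clipped rather than rejected).
#' @param profile `"mouse"` or `"human"`: sets the default genome length
#'   and the long-gene expression boost.
#' @param genome_length Haploid genome length; default 2.65e9 (mouse) or
#'   3.2e9 (human).
#' @param length_meanlog,length_sdlog Log-normal gene-span parameters.
#' @param min_length_bp,max_length_bp Clip window.
#' @param expr_sdlog Log-normal sdlog for raw expression.
#' @param long_gene_boost Exponent of the length-expression coupling;
#'   `NULL` picks 0.3 (mouse) / 0 (human).
#' @param seed Integer seed.
#' @param max_attempts Redraws allowed if total span exceeds the genome.
#' @return A `gene_catalog`.
#' @examples
#' cat <- simulate_gene_catalog(1000, seed = 7)
#' range(cat$length_bp)  # within [5000, 750000]
#' @export
simulate_gene_catalog <- function(n_genes, profile = c("mouse", "human"),
                                  genome_length = NULL,
                                  length_meanlog = log(25000),
                                  length_sdlog = 1.1,
                                  min_length_bp = 5000,
                                  max_length_bp = 750000,
                                  expr_sdlog = 1.5,
                                  long_gene_boost = NULL,
                                  seed = 1, max_attempts = 10) {
  profile <- match.arg(profile)
  if (is.null(genome_length)) {
    genome_length <- if (profile == "mouse") GENOME_LENGTH_MOUSE else GENOME_LENGTH_HUMAN
  }
  if (is.null(long_gene_boost)) {
    long_gene_boost <- if (profile == "mouse") 0.3 else 0
  }
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    len <- round(rlnorm(n_genes, meanlog = length_meanlog, sdlog = length_sdlog))
    len <- pmin(pmax(len, min_length_bp), max_length_bp)
    if (sum(as.numeric(len)) <= genome_length) break
    if (attempt == max_attempts) {
      abort("generated gene spans exceed the genome length; reduce n_genes")
    }
  }
  expr <- rlnorm(n_genes, meanlog = 0, sdlog = expr_sdlog) *
    (len / 25000)^long_gene_boost
  build_catalog(
    tibble(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      length_bp = as.integer(len),
      expression_raw = expr
    ),
    genome_length = genome_length
  )
}

#' Replicate catalogs with perturbed expression weights
#'
#' Emulates biological replicates (e.g. individually sequenced animals):
#' lengths are shared, raw expression is jittered multiplicatively
#' (log-normal, sdlog `expr_jitter`) per replicate.
#'
#' @param catalog A base catalog.
#' @param n Number of replicate catalogs.
#' @param expr_jitter sdlog of the multiplicative expression jitter.
#' @param seed Integer seed.
#' @return List of `gene_catalog`s.
#' @export
replicate_catalogs <- function(catalog, n = 3, expr_jitter = 0.1, seed = 1) {
  set.seed(seed)
  map(seq_len(n), function(i) {
    build_catalog(
      tibble(
        gene_id = catalog$gene_id,
        length_bp = catalog$length_bp,
        expression_raw = catalog$expression_raw *
          rlnorm(nrow(catalog), 0, expr_jitter)
      ),
      genome_length = genome_length(catalog)
    )
  })
}

#' Simulate a longitudinal transcription-loss series
#'
#' Forward model: observed loss at age t is
#' `100 * E[loss at M = round(rate * 7 * (age_weeks - t0_weeks))]` plus
#' Gaussian noise per animal; the reported series is the across-animal mean
#' with SEM.
#'
#' @param catalog A gene catalog.
#' @param rate True daily lesion rate (lesions/day).
#' @param ages_weeks Strictly increasing measurement ages in weeks.
#' @param t0_weeks Zero-loss age in weeks (default 0 = birth).
#' @param noise_sd Per-animal observation noise, percentage points.
#' @param n_animals Animals per time point.
#' @param genotype Label carried through to the series.
#' @param seed Integer seed.
#' @return Tibble: `genotype`, `age_weeks`, `loss_pct`, `sem_pct`.
#' @export
simulate_loss_series <- function(catalog, rate, ages_weeks, t0_weeks = 0,
                                 noise_sd = 2, n_animals = 3,
                                 genotype = "synthetic", seed = 1) {
  if (any(diff(ages_weeks) <= 0)) abort("ages must be strictly increasing")
  set.seed(seed)
  M <- vapply(ages_weeks, function(w) age_to_count(rate, w * 7, t0_weeks * 7),
              numeric(1))
  true_pct <- 100 * expected_loss(catalog, M)
  obs <- vapply(true_pct, function(mu) {
    draws <- mu + rnorm(n_animals, 0, noise_sd)
    c(mean(draws), sd(draws) / sqrt(n_animals))
  }, numeric(2))
  tibble(
    genotype = genotype,
    age_weeks = as.numeric(ages_weeks),
    loss_pct = pmin(pmax(obs[1, ], 0), 100),
    sem_pct = obs[2, ]
  )
}

#' Simulate EU dose-response observations
#'
#' Generates replicate-level normalized EU intensities at the given UV
#' doses from the closed-form model: the dose is converted to a lesion
#' density (x `uv_factor`) and a whole-genome count, the expected loss is
#' evaluated on the catalog, and intensity = 100 - loss% + Gaussian noise.
#'
#' @param catalog A gene catalog.
#' @param doses_J_m2 UV doses; include 0 for the reference condition.
#' @param uv_factor Lesions per 100 kb per J/m^2.
#' @param noise_sd Per-replicate noise, percentage points.
#' @param n_replicates Independent replicate experiments.
#' @param seed Integer seed.
#' @return Tibble: `replicate`, `dose` (J/m^2), `density` (TBLs/100 kb),
#'   `M`, `intensity_pct`, `true_loss_pct`.
#' @export
simulate_eu_dose_response <- function(catalog, doses_J_m2 = 0:6,
                                      uv_factor = UV_TBL_PER_100KB_PER_JM2,
                                      noise_sd = 2, n_replicates = 4,
                                      seed = 1) {
  set.seed(seed)
  density <- uv_dose_to_density(doses_J_m2, factor = uv_factor)
  M <- density_to_count(density, genome_length(catalog))
  true_pct <- 100 * expected_loss(catalog, M)
  tidyr::expand_grid(replicate = seq_len(n_replicates),
                     idx = seq_along(doses_J_m2)) |>
    mutate(
      dose = doses_J_m2[.data$idx],
      density = density[.data$idx],
      M = M[.data$idx],
      true_loss_pct = true_pct[.data$idx],
      intensity_pct = 100 - .data$true_loss_pct +
        rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    select(-"idx")
}

#' Simulate gene-body coverage profiles with known tilt
#'
#' `mode = "linear"` draws, per gene, a flat-plus-slope baseline profile
#' and an after-damage profile whose slope differs by exactly `tilt_truth`
#' (optionally with Gaussian noise). `mode = "truncation"` emulates
#' polymerases stalling at lesions: the after-damage profile decays
#' geometrically along the gene body at a per-bin stall probability
#' proportional to `lesion_density`, producing negative tilts that grow
#' with density.
#'
#' @param n_genes Number of genes.
#' @param bins Bins per gene body (default 20).
#' @param base_level Baseline RPKM.
#' @param slope_before Baseline slope (RPKM/bin).
#' @param tilt_truth Slope change applied in `"linear"` mode.
#' @param lesion_density Per-bin stall probability scale in
#'   `"truncation"` mode (0 = no damage).
#' @param noise_sd RPKM noise per bin.
#' @param mode `"linear"` or `"truncation"`.
#' @param seed Integer seed.
#' @return List of tibbles `before` and `after`, long format
#'   (`gene_id`, `bin_index`, `rpkm`).
#' @export
simulate_coverage_profiles <- function(n_genes, bins = 20, base_level = 10,
                                       slope_before = 0, tilt_truth = -0.2,
                                       lesion_density = 0.05, noise_sd = 0,
                                       mode = c("linear", "truncation"),
                                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(bins >= 3)
  set.seed(seed)
  idx <- seq_len(bins) - 1
  make <- function(level, slope, decay = 0) {
    prof <- pmax(level + slope * idx, 0) * (1 - decay)^idx
    pmax(prof + rnorm(bins, 0, noise_sd), 0)
  }
  # keep declining linear profiles positive end to end, so clipping never
  # distorts the constructed slopes
  min_slope <- min(slope_before, slope_before + tilt_truth, 0)
  offset <- -min_slope * (bins - 1)
  before <- list()
  after <- list()
  for (g in seq_len(n_genes)) {
    lev <- base_level * rlnorm(1, 0, 0.2) + offset
    before[[g]] <- tibble(gene_id = sprintf("g%04d", g), bin_index = idx,
                          rpkm = make(lev, slope_before))
    if (mode == "linear") {
      after[[g]] <- tibble(gene_id = sprintf("g%04d", g), bin_index = idx,
                           rpkm = make(lev, slope_before + tilt_truth))
    } else {
      stall <- min(lesion_density * rlnorm(1, 0, 0.3), 0.9)
      after[[g]] <- tibble(gene_id = sprintf("g%04d", g), bin_index = idx,
                           rpkm = make(lev, slope_before, decay = stall))
    }
  }
  list(before = bind_rows(before), after = bind_rows(after))
}

#' Simulate two-channel microscopy fields with ground truth
#'
#' Composes fields of disk nuclei on a dark background. Four constructed
#' classes mirror what liver imaging must filter:
#' * `hepatocyte` — area within the diploid window, normal EU;
#' * `too_small` — area below 24.4 um^2;
#' * `kupffer` — area just above the size gate but very dim EU;
#' * `polyploid` — area above 70 um^2, slightly brighter EU.
#' Each nucleus carries a concentric nucleolus occupying
#' `nucleolus_fraction` of its area: EU-bright (high rRNA signal) and
#' DNA-dim (chromatin-poor). Gaussian noise is added at
#' `signal / snr`.
#'
#' @param n_fields Number of fields.
#' @param nuclei_per_field Nuclei per field (placed on a jittered grid, so
#'   nuclei never touch).
#' @param class_fractions Named fractions over the four classes (summing
#'   to 1; counts are rounded deterministically).
#' @param eu_scale Hepatocyte nucleoplasmic EU level (arbitrary units).
#' @param nucleolus_fraction Nucleolar share of nuclear area.
#' @param snr Signal-to-noise ratio of the EU/DNA channels.
#' @param pixel_size_um Micrometres per pixel side.
#' @param seed Integer seed.
#' @return List with `fields` (each: `eu`, `dna`, `pixel_size_um`) and
#'   `truth` (tibble: `field`, `class`, `cx`, `cy`, `radius_px`,
#'   `area_um2`, `eu_level`, and the realized `nucleus_px`/`nucleolus_px`
#'   pixel counts, which carry the discretized ground truth for
#'   fraction-recovery checks).
#' @export
simulate_fields <- function(n_fields = 4, nuclei_per_field = 12,
                            class_fractions = c(hepatocyte = 0.55,
                                                too_small = 0.15,
                                                kupffer = 0.15,
                                                polyploid = 0.15),
                            eu_scale = 0.5, nucleolus_fraction = 0.1,
                            snr = 10, pixel_size_um = 0.5, seed = 1) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8)
  set.seed(seed)
  grid_cols <- ceiling(sqrt(nuclei_per_field))
  grid_rows <- ceiling(nuclei_per_field / grid_cols)
  cell <- 64L
  W <- grid_cols * cell
  H <- grid_rows * cell

  # per-class construction parameters (radius in px; EU relative level)
  class_radius <- list(hepatocyte = c(7, 9), too_small = c(4, 4),
                       kupffer = c(6, 6), polyploid = c(12, 13))
  class_eu <- c(hepatocyte = 1, too_small = 1, kupffer = 0.05, polyploid = 1.2)

  counts <- diff(c(0, round(cumsum(class_fractions) * nuclei_per_field)))
  names(counts) <- names(class_fractions)

  fields <- list()
  truth <- list()
  for (f in seq_len(n_fields)) {
    eu <- matrix(0.02, nrow = W, ncol = H)
    dna <- matrix(0.05, nrow = W, ncol = H)
    classes <- sample(rep(names(counts), counts))
    cells <- sample(grid_rows * grid_cols)[seq_along(classes)]
    rows <- list()
    for (k in seq_along(classes)) {
      cl <- classes[k]
      r <- round(runif(1, class_radius[[cl]][1], class_radius[[cl]][2]))
      ci <- (cells[k] - 1) %% grid_cols
      cj <- (cells[k] - 1) %/% grid_cols
      cx <- ci * cell + cell / 2 + round(runif(1, -6, 6))
      cy <- cj * cell + cell / 2 + round(runif(1, -6, 6))
      xs <- pmax(1, cx - r - 1):pmin(W, cx + r + 1)
      ys <- pmax(1, cy - r - 1):pmin(H, cy + r + 1)
      dist2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
      disk <- dist2 <= r^2
      r_nuc <- max(1, round(r * sqrt(nucleolus_fraction)))
      nucleolus <- dist2 <= r_nuc^2
      lvl <- eu_scale * class_eu[[cl]]
      eu_patch <- eu[xs, ys]
      eu_patch[disk] <- lvl
      eu_patch[nucleolus] <- pmax(2.5 * lvl, 0.3 * eu_scale)
      eu[xs, ys] <- eu_patch
      dna_patch <- dna[xs, ys]
      dna_patch[disk] <- 0.8
      dna_patch[nucleolus] <- 0.3
      dna[xs, ys] <- dna_patch
      rows[[k]] <- tibble(
        field = f, class = cl, cx = cx, cy = cy, radius_px = r,
        area_um2 = pi * r^2 * pixel_size_um^2, eu_level = lvl,
        nucleus_px = sum(disk), nucleolus_px = sum(nucleolus)
      )
    }
    eu <- pmax(eu + rnorm(length(eu), 0, eu_scale / snr), 0)
    dna <- pmax(dna + rnorm(length(dna), 0, 0.8 / snr), 0)
    fields[[f]] <- list(eu = eu, dna = dna, pixel_size_um = pixel_size_um)
    truth[[f]] <- bind_rows(rows)
  }
  list(fields = fields, truth = bind_rows(truth))
}
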