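#' Expected transcription loss after M lesions
#'
#' Closed form for the expected fraction of transcription lost when M
#' lesions are placed uniformly at random on the diploid double-stranded
#' genome:
#' \deqn{E[\omega_M] = \sum_j \alpha_j \left(1 - (1 - q_j)^M\right)}
#' with \eqn{q_j = l_j/(4L)} the probability that one lesion hits the
#' transcribed strand of one allele of gene j, and \eqn{\alpha_j} the
#' nascent-expression weight (\eqn{\sum \alpha = 1}). An allele is silenced
#' by its first transcribed-strand hit; each silenced allele removes half
#' the gene's transcription.
#'
#' The power is evaluated as `exp(M * log1p(-q))` for numerical stability at
#' large M and small q.
#'
#' @param catalog A [build_catalog()] gene catalog.
#' @param M Non-negative lesion count(s); vectorized.
#' @return Expected loss in `[0, 1]`, same length as `M`.
#' @examples
#' cat <- build_catalog(
#'   tibble::tibble(gene_id = "g", length_bp = 1e5, expression_raw = 1),
#'   genome_length = 3.2e9
#' )
#' expected_loss(cat, 0)       # 0
#' expected_loss(cat, 17600)   # small but positive
#' @export
expected_loss <- function(catalog, M) {
  if (any(M < 0)) abort("M must be non-negative")
  lq <- log1p(-catalog$q)
  vapply(M, function(m) sum(catalog$alpha * -expm1(m * lq)), numeric(1))
}

#' Expected-loss curve over a lesion or age grid
#'
#' Evaluates [expected_loss()] on a grid of lesion counts, or of ages when a
#' daily rate `r` is given (then `M = round(rate * (t - t0))` in days).
#' With several replicate catalogs (e.g. one per sequenced animal) the
#' per-point mean, SD and normal-approximation 95% CI across catalogs are
#' reported.
#'
#' @param catalogs A `gene_catalog` or list of them.
#' @param grid Lesion counts, or ages in days when `rate` is given.
#' @param rate Optional daily lesion accumulation rate (lesions/day).
#' @param t0 Zero-loss age in days (used only with `rate`).
#' @return A `loss_curve` tibble: `grid`, `M`, `expected_loss`, `sd`,
#'   `ci95_lo`, `ci95_hi`.
#' @export
loss_curve <- function(catalogs, grid, rate = NULL, t0 = 0) {
  if (inherits(catalogs, "gene_catalog")) catalogs <- list(catalogs)
  if (length(grid) == 0L) abort("empty grid")
  if (is.null(rate)) {
    M <- as.numeric(grid)
    if (any(M < 0)) abort("negative lesion counts in grid")
  } else {
    M <- vapply(grid, function(t) age_to_count(rate, t, t0), numeric(1))
  }
  per_cat <- vapply(catalogs, function(ct) expected_loss(ct, M),
                    numeric(length(M)))
  per_cat <- matrix(per_cat, nrow = length(M))
  mean_loss <- rowMeans(per_cat)
  sd_loss <- apply(per_cat, 1, sd)
  if (length(catalogs) == 1L) sd_loss <- rep(0, length(M))
  z <- qnorm(0.975)
  out <- tibble(
    grid = as.numeric(grid), M = M, expected_loss = mean_loss, sd = sd_loss,
    ci95_lo = pmax(0, mean_loss - z * sd_loss),
    ci95_hi = pmin(1, mean_loss + z * sd_loss)
  )
  class(out) <- c("loss_curve", class(out))
  out
}

#' Convert a UV-C dose to a lesion density
#'
#' One J/m^2 of UV-C induces about 0.55 transcription-blocking lesions per
#' 100 kb; the factor is configurable because it is an approximate
#' literature value.
#'
#' @param dose_J_m2 UV-C dose(s) in J/m^2.
#' @param factor Lesions per 100 kb per J/m^2.
#' @return Lesion density in TBLs per 100 kb.
#' @examples
#' uv_dose_to_density(6)  # 3.3
#' @export
uv_dose_to_density <- function(dose_J_m2, factor = UV_TBL_PER_100KB_PER_JM2) {
  if (any(dose_J_m2 < 0)) abort("negative UV dose")
  factor * dose_J_m2
}

#' Convert between lesion density and whole-genome lesion count
#'
#' Density is defined per 100 kb of the haploid genome length L, matching
#' the convention used for genome-wide totals (e.g. 0.55/100 kb on a 3.2 Gb
#' genome is 17,600 lesions), even though the placement probability uses 4L.
#'
#' @param density TBLs per 100 kb.
#' @param M Whole-genome lesion count.
#' @param genome_length Haploid genome length in bp.
#' @return `density_to_count()`: integer lesion count (rounded);
#'   `count_to_density()`: TBLs per 100 kb.
#' @examples
#' density_to_count(0.55, 3.2e9)    # 17600
#' count_to_density(193450, 2.65e9) # 7.3
#' @export
density_to_count <- function(density, genome_length) {
  if (any(density < 0)) abort("negative density")
  stopifnot(genome_length > 0)
  round(density * genome_length / 1e5)
}

#' @rdname density_to_count
#' @export
count_to_density <- function(M, genome_length) {
  if (any(M < 0)) abort("negative lesion count")
  stopifnot(genome_length > 0)
  M / (genome_length / 1e5)
}

#' Lesion count reached at a given age
#'
#' Under constant accumulation at `rate` lesions/day starting from the
#' zero-loss age `t0`, the count at age `t` is `round(rate * (t - t0))`
#' (half-away-from-zero; lesions are integer events).
#'
#' @param rate Daily lesion accumulation rate (lesions/day), >= 0.
#' @param t Age in days.
#' @param t0 Zero-loss age in days (default 0 = birth).
#' @return Integer lesion count M.
#' @examples
#' age_to_count(62, 728, 49)  # 42098
#' @export
age_to_count <- function(rate, t, t0 = 0) {
  if (rate < 0) abort("rate must be non-negative")
  if (any(t < t0)) abort("age t earlier than zero-loss age t0")
  round_half_up(rate * (t - t0))
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
autoplot.loss_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = 100 * .data$expected_loss)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 100 * .data$ci95_lo, ymax = 100 * .data$ci95_hi),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "lesions (or age grid)", y = "expected transcription loss (%)") +
    ggplot2::theme_minimal()
}
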