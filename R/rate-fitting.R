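#' Calibrate the daily lesion accumulation rate
#'
#' Finds the constant rate `r` (lesions/day) such that the model's expected
#' loss at the calibration time point best matches the observed loss there:
#' `r = M*/dt` where `M*` is the integer lesion count minimizing
#' `|E[loss at M] - observed|`. Because expected loss is monotone in M the
#' search is an integer bisection (bracket doubling, then halving down to
#' adjacent integers or `|E - target| <= tol`).
#'
#' Two calibration conventions are supported, matching how longitudinal
#' series with and without an early loss signal are handled:
#' * `calibrate_on = "first"` — calibrate at the first time point and
#'   validate on the later ones; accumulation is counted from `t0` (default
#'   birth, `t0_weeks = 0`). Used for repair-deficient series whose first
#'   measurement already shows loss.
#' * `calibrate_on = "last"` — calibrate at the last point and predict the
#'   earlier ones; `t0` defaults to the first measured age, which is assumed
#'   lesion-free. Used for wildtype-style series where the first point shows
#'   no loss.
#'
#' @param catalog A gene catalog, or a list of replicate catalogs (e.g. one
#'   per sequenced animal) — then `r` is fitted per catalog and reported as
#'   mean with SD.
#' @param series Tibble with columns `age_weeks`, `loss_pct` and optionally
#'   `sem_pct`, `genotype`.
#' @param calibrate_on `"first"` or `"last"`.
#' @param t0_weeks Zero-loss age in weeks; `NULL` picks the convention
#'   default described above.
#' @param tol Absolute tolerance on expected loss during bisection.
#' @return A `rate_fit` object: fields `r` (mean lesions/day), `r_sd`,
#'   `r_per_catalog`, `calibration_age_weeks`, `t0_weeks`, `validation`
#'   (see [validate_rate()]), `series`, `genotype`.
#' @examples
#' cat <- simulate_gene_catalog(n_genes = 500, seed = 1)
#' ser <- simulate_loss_series(cat, rate = 2000,
#'   ages_weeks = c(7, 14, 18), noise_sd = 0, seed = 1)
#' fit <- calibrate_rate(cat, ser)
#' round(fit$r / 2000, 2)  # ~1
#' @export
calibrate_rate <- function(catalog, series, calibrate_on = c("first", "last"),
                           t0_weeks = NULL, tol = 1e-6) {
  calibrate_on <- match.arg(calibrate_on)
  series <- as_tibble(series)
  if (!all(c("age_weeks", "loss_pct") %in% names(series))) {
    abort("series needs columns 'age_weeks' and 'loss_pct'")
  }
  if (any(diff(series$age_weeks) <= 0)) abort("ages must be strictly increasing")
  if (any(series$loss_pct < 0 | series$loss_pct > 100)) {
    abort("loss_pct out of [0, 100]")
  }
  catalogs <- if (inherits(catalog, "gene_catalog")) list(catalog) else catalog
  cal_idx <- if (calibrate_on == "first") 1L else nrow(series)
  if (is.null(t0_weeks)) {
    t0_weeks <- if (calibrate_on == "last") series$age_weeks[1] else 0
  }
  cal_age <- series$age_weeks[cal_idx]
  dt_days <- (cal_age - t0_weeks) * 7
  if (dt_days <= 0) abort("calibration point coincides with t0 (dt = 0)")
  target <- series$loss_pct[cal_idx] / 100

  r_per_catalog <- vapply(catalogs, function(ct) {
    if (target >= sum(ct$alpha)) {
      abort("observed loss at calibration point exceeds the model's asymptote sum(alpha)")
    }
    if (target <= 0) return(0)
    invert_loss(ct, target, tol) / dt_days
  }, numeric(1))

  fit <- structure(
    list(
      r = mean(r_per_catalog),
      r_sd = if (length(r_per_catalog) > 1L) sd(r_per_catalog) else 0,
      r_per_catalog = r_per_catalog,
      calibration_age_weeks = cal_age,
      calibrate_on = calibrate_on,
      t0_weeks = t0_weeks,
      genotype = if ("genotype" %in% names(series)) series$genotype[1] else NA_character_,
      series = series,
      catalogs = catalogs
    ),
    class = "rate_fit"
  )
  fit$validation <- validate_rate(fit)
  fit
}

# smallest-error integer M with E[loss] ~ target; monotone bisection
invert_loss <- function(catalog, target, tol = 1e-6) {
  lo <- 0
  hi <- 1
  while (expected_loss(catalog, hi) < target) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e15) abort("target loss unreachable")
  }
  while (hi - lo > 1L) {
    mid <- floor((lo + hi) / 2)
    e <- expected_loss(catalog, mid)
    if (abs(e - target) <= tol) return(mid)
    if (e < target) lo <- mid else hi <- mid
  }
  if (abs(expected_loss(catalog, lo) - target) <=
      abs(expected_loss(catalog, hi) - target)) lo else hi
}

#' Validate a calibrated rate on the held-out time points
#'
#' For every non-calibration time point, compares the model's predicted
#' loss (using the fitted mean rate) with the observed loss:
#' absolute error (percentage points) `= |100 E - loss_pct|`, relative
#' error `= absolute / loss_pct * 100`. Both are reported as magnitudes.
#'
#' @param fit A `rate_fit`.
#' @return Tibble: `age_weeks`, `M`, `predicted_pct`, `observed_pct`,
#'   `abs_error_pct`, `rel_error_pct`, `role` ("calibration"/"validation").
#' @export
validate_rate <- function(fit) {
  stopifnot(inherits(fit, "rate_fit"))
  series <- fit$series
  cal_idx <- if (fit$calibrate_on == "first") 1L else nrow(series)
  M <- vapply(series$age_weeks, function(w) {
    age_to_count(fit$r, w * 7, fit$t0_weeks * 7)
  }, numeric(1))
  pred <- 100 * rowMeans(vapply(
    fit$catalogs, function(ct) expected_loss(ct, M), numeric(length(M))
  ) |> matrix(nrow = length(M)))
  tibble(
    age_weeks = series$age_weeks,
    M = M,
    predicted_pct = pred,
    observed_pct = series$loss_pct,
    abs_error_pct = abs(pred - series$loss_pct),
    rel_error_pct = ifelse(series$loss_pct > 0,
                           abs(pred - series$loss_pct) / series$loss_pct * 100,
                           NA_real_),
    role = ifelse(seq_len(nrow(series)) == cal_idx, "calibration", "validation")
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit>%s r = %.0f lesions/day (SD %.0f across %d catalog%s)\n",
              if (is.na(x$genotype)) "" else paste0(" [", x$genotype, "]"),
              x$r, x$r_sd, length(x$r_per_catalog),
              if (length(x$r_per_catalog) == 1L) "" else "s"))
  cat(sprintf("  calibrated on the %s point (%g weeks), t0 = %g weeks\n",
              x$calibrate_on, x$calibration_age_weeks, x$t0_weeks))
  v <- x$validation[x$validation$role == "validation", ]
  if (nrow(v)) {
    cat(sprintf("  validation: mean |error| %.1f pct points, mean relative %.1f%%\n",
                mean(v$abs_error_pct), mean(v$rel_error_pct, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
tidy.rate_fit <- function(x, ...) x$validation

#' @export
glance.rate_fit <- function(x, ...) {
  v <- x$validation[x$validation$role == "validation", ]
  tibble(
    genotype = x$genotype,
    r = x$r, r_sd = x$r_sd, n_catalogs = length(x$r_per_catalog),
    calibration_age_weeks = x$calibration_age_weeks, t0_weeks = x$t0_weeks,
    mean_abs_error_pct = if (nrow(v)) mean(v$abs_error_pct) else NA_real_,
    mean_rel_error_pct = if (nrow(v)) mean(v$rel_error_pct, na.rm = TRUE) else NA_real_
  )
}

#' @export
autoplot.rate_fit <- function(object, ...) {
  obs <- object$series
  grid_w <- seq(object$t0_weeks, max(obs$age_weeks), length.out = 100)
  curve <- loss_curve(object$catalogs, grid_w * 7, rate = object$r,
                      t0 = object$t0_weeks * 7)
  curve$age_weeks <- grid_w
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = curve,
      ggplot2::aes(x = .data$age_weeks, y = 100 * .data$expected_loss)
    ) +
    ggplot2::geom_point(
      data = obs, ggplot2::aes(x = .data$age_weeks, y = .data$loss_pct),
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "age (weeks)", y = "transcription loss (%)",
                  title = sprintf("fitted rate: %.0f lesions/day", object$r)) +
    ggplot2::theme_minimal()
}

#' Repair-capacity arithmetic between two genotypes
#'
#' Compares daily unrepaired-lesion rates of a repair-deficient genotype
#' against a reference (typically the fully repair-deficient genotype, or a
#' deficient genotype against wildtype): the daily difference is the number
#' of lesions per day the less-deficient genotype still repairs, and the
#' percentages express retained repair capacity and the persisting fraction.
#'
#' @param r_deficient Daily rate of the genotype of interest (lesions/day).
#' @param r_reference Daily rate of the reference genotype, > 0.
#' @return Tibble: `daily_difference`, `percent_of_reference` (repaired
#'   share, `= 100 * (r_ref - r_def)/r_ref`), `percent_persisting`
#'   (`= 100 * r_def/r_ref`), `percent_repaired` (`= 100 - persisting`).
#' @examples
#' repair_capacity(1621, 4978)  # difference 3357, 67.4% retained capacity
#' repair_capacity(62, 4978)    # 1.2% persisting, 98.8% repaired
#' @export
repair_capacity <- function(r_deficient, r_reference) {
  if (r_reference <= 0) abort("reference rate must be positive")
  diff <- r_reference - r_deficient
  persisting <- r_deficient / r_reference * 100
  tibble(
    daily_difference = diff,
    percent_of_reference = diff / r_reference * 100,
    percent_persisting = persisting,
    percent_repaired = 100 - persisting
  )
}

#' Project a rate under partial residual repair activity
#'
#' If a genotype retains a fraction of the reference repair capacity, its
#' projected daily unrepaired-lesion rate is
#' `r_reference * (1 - residual_fraction)`, rounded to whole lesions.
#'
#' @param r_reference Reference daily rate (lesions/day).
#' @param residual_fraction Retained repair capacity in `[0, 1]`.
#' @return Projected lesions/day (integer).
#' @examples
#' project_residual_rate(4978, 0.075)  # 4605
#' @export
project_residual_rate <- function(r_reference, residual_fraction) {
  if (residual_fraction < 0 || residual_fraction > 1) {
    abort("residual_fraction must be in [0, 1]")
  }
  round_half_up(r_reference * (1 - residual_fraction))
}
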