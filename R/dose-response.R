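#' Normalize EU intensities to the untreated control
#'
#' Each replicate experiment is scaled so its own 0-dose (reference)
#' condition sits at 100%, before pooling across replicates.
#'
#' @param obs Tibble with columns `replicate`, `dose` (numeric; J/m^2 or
#'   TBLs/100 kb) and `intensity`.
#' @param reference_dose The control dose (default 0).
#' @return `obs` with an added `intensity_pct` column.
#' @export
normalize_eu <- function(obs, reference_dose = 0) {
  obs <- as_tibble(obs)
  need <- c("replicate", "dose", "intensity")
  if (!all(need %in% names(obs))) {
    abort(paste0("obs needs columns: ", paste(need, collapse = ", ")))
  }
  obs |>
    group_by(.data$replicate) |>
    mutate(intensity_pct = {
      ref <- .data$intensity[.data$dose == reference_dose]
      if (length(ref) == 0L) abort("replicate lacks the reference condition")
      .data$intensity / mean(ref) * 100
    }) |>
    ungroup()
}

#' Convert EU intensity to transcription loss
#'
#' Transcription loss is `100% - normalized EU intensity`; standard errors
#' propagate unchanged. Works on replicate-level tables (computing the
#' per-dose mean and SEM across replicates) or on pre-summarized tables
#' carrying `intensity_pct` and `sem_pct`.
#'
#' @param obs Tibble with `dose` and `intensity_pct`, plus either
#'   `replicate` (replicate-level) or `sem_pct` (summarized).
#' @return Tibble: `dose`, `loss_pct`, `sem_pct`, `n`.
#' @examples
#' eu_to_loss(tibble::tibble(dose = c(0, 1), intensity_pct = c(100, 85),
#'                           sem_pct = c(0, 5.6)))
#' @export
eu_to_loss <- function(obs) {
  obs <- as_tibble(obs)
  if (!all(c("dose", "intensity_pct") %in% names(obs))) {
    abort("obs needs columns 'dose' and 'intensity_pct'")
  }
  if ("replicate" %in% names(obs) && anyDuplicated(obs$dose)) {
    obs |>
      group_by(.data$dose) |>
      summarise(
        loss_pct = 100 - mean(.data$intensity_pct),
        sem_pct = if (n() > 1L) sd(.data$intensity_pct) / sqrt(n()) else 0,
        n = n(), .groups = "drop"
      )
  } else {
    tibble(
      dose = obs$dose,
      loss_pct = 100 - obs$intensity_pct,
      sem_pct = obs$sem_pct %||% rep(0, nrow(obs)),
      n = rep(1L, nrow(obs))
    )
  }
}

#' Fit the dose-response polynomial
#'
#' Ordinary least squares of transcription loss on lesion density with a
#' raw polynomial design of degree 1 (linear) or 3 (the third-order
#' polynomial that captures the plateau at high lesion densities, where new
#' lesions increasingly strike already-silenced genes).
#'
#' @param data Tibble with the predictor and response columns.
#' @param degree 1 or 3.
#' @param x,y Column names (default `"density"`, `"loss_pct"`).
#' @return A `dose_response_fit`: list with the `lm` fit, `degree`,
#'   `coefficients` (ascending powers), `fitted`, `residuals`, `data`.
#' @export
fit_dose_response <- function(data, degree = 3, x = "density", y = "loss_pct") {
  data <- as_tibble(data)
  if (!degree %in% c(1, 3)) abort("degree must be 1 or 3")
  if (!all(c(x, y) %in% names(data))) abort("predictor/response columns missing")
  xs <- data[[x]]
  ys <- data[[y]]
  if (length(unique(xs)) < degree + 1) {
    abort(sprintf("need at least %d distinct %s values for degree %d",
                  degree + 1, x, degree))
  }
  fit <- lm(ys ~ stats::poly(xs, degree = degree, raw = TRUE))
  if (any(is.na(coef(fit)))) abort("rank-deficient polynomial design")
  structure(
    list(
      lm = fit, degree = degree,
      coefficients = setNames(as.numeric(coef(fit)), paste0("x^", 0:degree)),
      fitted = as.numeric(stats::fitted(fit)),
      residuals = as.numeric(stats::residuals(fit)),
      data = tibble(density = xs, loss_pct = ys),
      x = x, y = y
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> degree %d, %d points, RSS %.4g\n",
              x$degree, nrow(x$data), sum(x$residuals^2)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = as.numeric(x$coefficients))
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(degree = x$degree, r.squared = s$r.squared,
         sigma = s$sigma, rss = sum(x$residuals^2),
         nobs = nrow(x$data))
}

#' @export
autoplot.dose_response_fit <- function(object, ...) {
  grid <- tibble(density = seq(min(object$data$density),
                               max(object$data$density), length.out = 200))
  grid$loss_pct <- predict_dose_response(object, grid$density)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$density, y = .data$loss_pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "TBLs per 100 kb", y = "transcription loss (%)") +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted dose-response polynomial
#' @param fit A `dose_response_fit`.
#' @param density Lesion densities at which to evaluate.
#' @return Predicted loss (%).
#' @export
predict_dose_response <- function(fit, density) {
  powers <- outer(density, 0:fit$degree, `^`)
  as.numeric(powers %*% fit$coefficients)
}

#' Low-dose transcription loss per unit lesion density
#'
#' The slope of the linear dose-response fit: percentage points of
#' transcription loss per additional TBL per 100 kb.
#'
#' @param fit A degree-1 `dose_response_fit`.
#' @return Slope in %/(TBL/100 kb).
#' @export
per_tbl_slope <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$degree != 1) abort("per_tbl_slope needs the linear (degree-1) fit")
  as.numeric(fit$coefficients["x^1"])
}

#' Model-vs-data error table
#'
#' For each non-reference dose, tabulates the deviation of model-predicted
#' transcription loss from the measured loss: absolute error in percentage
#' points (reported as magnitude), relative error in % of the measured
#' loss, and each expressed in multiples of the experimental SEM. Doses
#' with zero measured loss have undefined relative error (`NA`, excluded
#' from the relative-error mean).
#'
#' @param model_loss_pct Model-predicted loss (%) per dose.
#' @param data Tibble with `dose`, `loss_pct` and `sem_pct` (from
#'   [eu_to_loss()]), on the same dose grid.
#' @return An `error_table` tibble: `dose`, `model_pct`, `data_pct`,
#'   `sem_pct`, `abs_error_pct`, `abs_error_sems`, `rel_error_pct`,
#'   `rel_error_sems`.
#' @examples
#' dose_error_table(50, tibble::tibble(dose = 1, loss_pct = 40, sem_pct = 5))
#' @export
dose_error_table <- function(model_loss_pct, data) {
  data <- as_tibble(data)
  if (length(model_loss_pct) != nrow(data)) {
    abort("model and data dose grids differ in length")
  }
  abs_err <- abs(model_loss_pct - data$loss_pct)
  rel_err <- ifelse(data$loss_pct > 0, abs_err / data$loss_pct * 100, NA_real_)
  out <- tibble(
    dose = data$dose,
    model_pct = model_loss_pct,
    data_pct = data$loss_pct,
    sem_pct = data$sem_pct,
    abs_error_pct = abs_err,
    abs_error_sems = ifelse(data$sem_pct > 0, abs_err / data$sem_pct, NA_real_),
    rel_error_pct = rel_err,
    rel_error_sems = ifelse(data$sem_pct > 0, rel_err / data$sem_pct, NA_real_)
  )
  class(out) <- c("error_table", class(out))
  out
}

#' Column means of an error table
#'
#' @param tbl An `error_table` (or any tibble with its error columns).
#' @return One-row tibble of across-dose means; `NA` relative errors
#'   (zero-loss doses) are excluded from their mean.
#' @export
error_table_means <- function(tbl) {
  tibble(
    mean_abs_error_pct = mean(tbl$abs_error_pct),
    mean_abs_error_sems = mean(tbl$abs_error_sems, na.rm = TRUE),
    mean_rel_error_pct = mean(tbl$rel_error_pct, na.rm = TRUE),
    mean_rel_error_sems = mean(tbl$rel_error_sems, na.rm = TRUE)
  )
}
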