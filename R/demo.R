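#' One-shot demonstration run on synthetic data
#'
#' Exercises every pipeline stage on generated inputs and writes a plain
#' report plus the intermediate TSVs to `out_dir`: catalog construction,
#' expectation-model conversions (the dose-to-count arithmetic and the
#' repair-capacity arithmetic recomputed from built-in reference rates),
#' Monte-Carlo vs closed-form agreement, dose-response fitting with its
#' error table, rate calibration with validation, cohort tilt on
#' truncation-mode profiles, and gated image quantification. Every
#' exclusion (filtered genes, gated nuclei) is counted in the report. The
#' run is deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving every stochastic stage.
#' @param n_genes Catalog size for the demo (kept modest for speed).
#' @return Invisibly, a named list of the key computed quantities.
#' @export
run_demo <- function(out_dir = tempfile("txstress_demo_"), seed = 1,
                     n_genes = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    lines <<- c(lines, msg)
    inform(msg)
  }
  say("txstress demo (seed %d)", seed)

  # catalog
  cat_m <- simulate_gene_catalog(n_genes, profile = "mouse", seed = seed)
  write_catalog(cat_m, file.path(out_dir, "catalog.tsv"))
  say("catalog: %d genes, L = %.3g bp, sum(alpha) = %.6f",
      nrow(cat_m), genome_length(cat_m), sum(cat_m$alpha))

  # printed-arithmetic conversions
  n1 <- density_to_count(uv_dose_to_density(1), GENOME_LENGTH_HUMAN)
  n6 <- density_to_count(uv_dose_to_density(6), GENOME_LENGTH_HUMAN)
  say("UV conversions (human, L = 3.2 Gb): 1 J/m2 -> %d lesions; 6 J/m2 -> %d",
      n1, n6)
  rc <- repair_capacity(1621, 4978)
  say("repair capacity 1621 vs 4978/day: difference %.0f/day, %.1f%% retained",
      rc$daily_difference, rc$percent_of_reference)
  wt <- repair_capacity(62, 4978)
  say("wildtype vs 4978/day: %.1f%% persisting, %.1f%% repaired",
      wt$percent_persisting, wt$percent_repaired)

  # Monte-Carlo check
  sim <- simulate_lesions(cat_m, M = 50000, replicates = 2000, seed = seed)
  closed <- expected_loss(cat_m, 50000)
  say("M = 50,000: closed form %.4f, Monte-Carlo %.4f (SE %.5f)",
      closed, sim$mean, sim$se)

  # dose-response
  obs <- simulate_eu_dose_response(cat_m, doses_J_m2 = 0:6, noise_sd = 2,
                                   seed = seed)
  losses <- eu_to_loss(obs)
  readr::write_tsv(losses, file.path(out_dir, "dose_response.tsv"))
  dens <- uv_dose_to_density(losses$dose)
  fit3 <- fit_dose_response(tibble(density = dens, loss_pct = losses$loss_pct),
                            degree = 3)
  model_pct <- 100 * expected_loss(cat_m, density_to_count(dens, genome_length(cat_m)))
  etab <- dose_error_table(model_pct, tibble(dose = dens,
                                             loss_pct = losses$loss_pct,
                                             sem_pct = losses$sem_pct))
  etab <- etab[dens > 0, ]
  readr::write_tsv(etab, file.path(out_dir, "error_table.tsv"))
  em <- error_table_means(etab)
  say("dose-response: cubic RSS %.3g; model-vs-data mean |error| %.2f pct points",
      sum(fit3$residuals^2), em$mean_abs_error_pct)

  # rate calibration
  ser <- simulate_loss_series(cat_m, rate = 2315, ages_weeks = c(10, 16, 21),
                              noise_sd = 2, seed = seed)
  rf <- calibrate_rate(cat_m, ser)
  readr::write_tsv(tidy(rf), file.path(out_dir, "rate_validation.tsv"))
  say("rate calibration (true 2,315/day): fitted %.0f/day; mean validation |error| %.2f pct points",
      rf$r, mean(tidy(rf)$abs_error_pct[tidy(rf)$role == "validation"]))

  # tilt
  prof <- simulate_coverage_profiles(50, mode = "truncation",
                                     lesion_density = 0.05, seed = seed)
  ts <- tilt_summary(cohort_tilt(prof$before, prof$after))
  say("tilt (truncation cohort): mean %.3f RPKM/bin, %.0f%% of genes negative",
      ts$mean_tilt, 100 * ts$fraction_negative)

  # imaging
  fx <- simulate_fields(n_fields = 2, seed = seed)
  meas <- bind_rows(lapply(seq_along(fx$fields), function(i) {
    mutate(quantify_field(fx$fields[[i]]), field = i)
  }))
  say("imaging: %d nuclei segmented, %d pass gates (%d too small, %d polyploid-like, %d dim, %d low circularity)",
      nrow(meas), sum(meas$pass), sum(meas$too_small),
      sum(meas$too_large_polyploid), sum(meas$low_eu_kupffer_like),
      sum(meas$low_circularity))
  readr::write_tsv(meas, file.path(out_dir, "nuclei.tsv"))

  writeLines(lines, file.path(out_dir, "report.txt"))
  say("report written to %s", file.path(out_dir, "report.txt"))
  invisible(list(
    conversions = c(dose1 = n1, dose6 = n6),
    repair = rc, wildtype = wt,
    mc = c(closed = closed, sim = sim$mean),
    error_means = em, rate_fit = rf, tilt = ts,
    out_dir = out_dir
  ))
}
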