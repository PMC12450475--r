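test_that("Otsu segmentation finds the constructed nuclei and fills holes", {
  fx <- simulate_fields(n_fields = 1, nuclei_per_field = 6,
                        class_fractions = c(hepatocyte = 1, too_small = 0,
                                            kupffer = 0, polyploid = 0),
                        seed = 41)
  f <- fx$fields[[1]]
  labels <- segment_nuclei(f$dna)
  expect_equal(max(labels), 6)
  # known-radius disks: pixel area within 5% of pi r^2 (the DNA-dim
  # nucleolar hole must have been filled)
  truth <- fx$truth
  for (k in seq_len(nrow(truth))) {
    lb <- labels[truth$cx[k], truth$cy[k]]
    expect_gt(lb, 0)
    expect_equal(sum(labels == lb) / (pi * truth$radius_px[k]^2), 1,
                 tolerance = 0.05)
  }
  expect_error(segment_nuclei(matrix(1, 10, 10)), "constant")
})

test_that("moment-preserving threshold recovers a two-level split exactly", {
  # Tsai's criterion is exact for a two-delta histogram
  x <- c(rep(0.2, 900), rep(0.8, 100))
  thr <- txstress:::threshold_moments(x)
  expect_true(thr >= 0.2 && thr < 0.8)
  expect_equal(mean(x > thr), 0.1, tolerance = 0.005)
})

test_that("nucleolus segmentation recovers the constructed nucleolar fraction", {
  fx <- simulate_fields(n_fields = 1, nuclei_per_field = 6,
                        class_fractions = c(hepatocyte = 1, too_small = 0,
                                            kupffer = 0, polyploid = 0),
                        nucleolus_fraction = 0.1, seed = 42)
  f <- fx$fields[[1]]
  labels <- segment_nuclei(f$dna)
  nuc <- segment_nucleoli(f$eu, labels)
  truth_frac <- sum(fx$truth$nucleolus_px) / sum(fx$truth$nucleus_px)
  got_frac <- sum(nuc) / sum(labels > 0)
  expect_lt(abs(got_frac - truth_frac), 0.03)
  # a uniform interior yields a near-empty nucleoli mask
  flat <- f
  flat$eu[labels > 0] <- 0.5
  nuc_flat <- segment_nucleoli(flat$eu, labels)
  expect_lt(sum(nuc_flat) / sum(labels > 0), 0.1)
  # empty nucleus mask is not an error
  expect_equal(sum(segment_nucleoli(f$eu, labels * 0L)), 0)
})

test_that("species gates flag constructed classes correctly", {
  fx <- simulate_fields(n_fields = 6, nuclei_per_field = 12, seed = 43)
  joined <- dplyr::bind_rows(lapply(seq_along(fx$fields), function(i) {
    f <- fx$fields[[i]]
    labels <- segment_nuclei(f$dna)
    m <- quantify_field(f)
    tr <- dplyr::filter(fx$truth, field == i)
    tr$label <- mapply(function(x, y) labels[x, y], tr$cx, tr$cy)
    dplyr::inner_join(tr, m, by = "label")
  }))
  acc <- joined |>
    dplyr::group_by(class) |>
    dplyr::summarise(
      flagged_small = mean(too_small),
      flagged_poly = mean(too_large_polyploid),
      flagged_dim = mean(low_eu_kupffer_like),
      kept = mean(pass)
    )
  expect_gte(acc$flagged_small[acc$class == "too_small"], 0.95)
  expect_gte(acc$flagged_poly[acc$class == "polyploid"], 0.95)
  expect_gte(acc$flagged_dim[acc$class == "kupffer"], 0.95)
  expect_gte(acc$kept[acc$class == "hepatocyte"], 0.95)
})

test_that("boundary areas respect the mouse gates and disks are near-circular", {
  # synthetic measurement rows exercise the gate arithmetic directly
  meas_area <- function(a) tibble::tibble(
    label = 1L, area_um2 = a, circularity = 0.95,
    nucleoplasm_mean_eu = 1, too_small = a < 24.4,
    too_large_polyploid = a > 70, low_circularity = FALSE,
    empty_nucleoplasm = FALSE)
  p <- species_profile("mouse")
  expect_true(meas_area(20)$too_small)
  expect_true(meas_area(80)$too_large_polyploid)
  expect_false(meas_area(50)$too_small || meas_area(50)$too_large_polyploid)
  # measured circularity of constructed disks is ~1
  fx <- simulate_fields(n_fields = 1, nuclei_per_field = 6,
                        class_fractions = c(hepatocyte = 1, too_small = 0,
                                            kupffer = 0, polyploid = 0),
                        seed = 44)
  m <- quantify_field(fx$fields[[1]])
  expect_true(all(m$circularity > 0.85 & m$circularity <= 1))
})

test_that("human profile admits larger nuclei than mouse", {
  p_m <- species_profile("mouse")
  p_h <- species_profile("human")
  expect_equal(c(p_m$min_area_um2, p_m$max_area_um2), c(24.4, 70))
  expect_equal(c(p_h$min_area_um2, p_h$max_area_um2), c(24.4, 250))
  expect_gt(p_m$min_circularity, p_h$min_circularity)
})

test_that("field summary is the median of passing nuclei; normalization anchors the reference", {
  meas <- tibble::tibble(
    label = 1:4, area_um2 = 50, circularity = 0.9,
    nucleoplasm_mean_eu = c(10, 10, 10, 99),
    too_small = FALSE, too_large_polyploid = c(FALSE, FALSE, FALSE, TRUE),
    low_circularity = FALSE, empty_nucleoplasm = FALSE,
    low_eu_kupffer_like = FALSE,
    pass = c(TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(summarize_field(meas), 10)
  expect_warning(summarize_field(dplyr::mutate(meas, pass = FALSE)), "excluded")
  summaries <- tibble::tibble(sample = c("ref", "ref", "trt"),
                              field_summary = c(10, 12, 7.7))
  out <- normalize_cohort(summaries, "ref")
  expect_equal(out$normalized_pct, c(10, 12, 7.7) / 11 * 100)
})

test_that("intensity linearity: scaling EU scales summaries; normalized values invariant", {
  fx <- simulate_fields(n_fields = 1, seed = 45)
  f <- fx$fields[[1]]
  m1 <- quantify_field(f)
  f2 <- f
  f2$eu <- f$eu * 3
  m2 <- quantify_field(f2)
  expect_equal(m2$nucleoplasm_mean_eu, 3 * m1$nucleoplasm_mean_eu,
               tolerance = 1e-6)
  expect_equal(summarize_field(m2), 3 * summarize_field(m1), tolerance = 1e-6)
})

test_that("constructed 30% intensity reduction is recovered within 3 points", {
  ref <- simulate_fields(n_fields = 3, eu_scale = 0.5, seed = 46)
  trt <- simulate_fields(n_fields = 3, eu_scale = 0.35, seed = 47)
  summ <- function(fx, name) tibble::tibble(
    sample = name,
    field_summary = sapply(fx$fields,
                           function(f) summarize_field(quantify_field(f))))
  res <- normalize_cohort(dplyr::bind_rows(summ(ref, "ref"),
                                           summ(trt, "trt")), "ref")
  trt_mean <- mean(res$normalized_pct[res$sample == "trt"])
  expect_lt(abs(trt_mean - 70), 3)
})
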