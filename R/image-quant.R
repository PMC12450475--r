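#' Species quantification profiles
#'
#' Size and shape gates applied to segmented nuclei before intensity
#' summaries:
#' * `mouse` (hepatocytes): area 24.4--70 um^2, circularity > 0.7, with a
#'   low-EU gate that removes Kupffer-like cells (default cutoff: 20% of
#'   the field's median nucleoplasmic EU among size/shape-passing nuclei —
#'   an artifact-chosen default, the published analyses draw it per
#'   dataset). Nuclei above 70 um^2 are flagged polyploid-like: the loss
#'   model assumes diploidy.
#' * `human` (fibroblasts): area 24.4--250 um^2, circularity > 0.6, no
#'   low-EU gate.
#'
#' @param species `"mouse"` or `"human"`.
#' @param low_eu_fraction Kupffer gate as a fraction of the field median
#'   (mouse only).
#' @return A list of gate parameters.
#' @export
species_profile <- function(species = c("mouse", "human"), low_eu_fraction = 0.2) {
  species <- match.arg(species)
  if (species == "mouse") {
    list(species = "mouse", min_area_um2 = 24.4, max_area_um2 = 70,
         min_circularity = 0.7, low_eu_fraction = low_eu_fraction)
  } else {
    list(species = "human", min_area_um2 = 24.4, max_area_um2 = 250,
         min_circularity = 0.6, low_eu_fraction = NA_real_)
  }
}

#' Segment nuclei from the DNA channel
#'
#' Global Otsu threshold on the (rescaled) DNA/Hoechst channel, hole
#' filling, connected-component labeling. Touching nuclei are not split
#' (no watershed); the synthetic generator places nuclei apart.
#'
#' @param dna Numeric matrix, non-negative DNA-stain intensities.
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dna) {
  rng <- range(dna)
  if (diff(rng) == 0) abort("constant DNA channel: threshold undefined")
  img <- EBImage::Image((dna - rng[1]) / diff(rng))
  thr <- EBImage::otsu(img, range = c(0, 1))
  mask <- EBImage::fillHull(img > thr)
  EBImage::imageData(EBImage::bwlabel(mask))
}

# Tsai moment-preserving threshold on [0,1] intensities (the 'Moments'
# autothreshold): picks the gray level whose below-threshold pixel fraction
# equals the fraction p0 of the two-level image preserving the first three
# histogram moments.
threshold_moments <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  lev <- (seq_len(n_bins) - 0.5) / n_bins
  m1 <- sum(lev * p); m2 <- sum(lev^2 * p); m3 <- sum(lev^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) return(m1)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(m1)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)  # fraction of pixels below threshold
  p0 <- min(max(p0, 0), 1)
  cum <- cumsum(p)
  idx <- which(cum >= p0)[1]
  if (is.na(idx)) return(lev[n_bins])
  lev[idx]
}

#' Segment nucleoli within nuclei
#'
#' Nucleoli are the bright rRNA-transcription foci in the EU channel (and
#' DNA-poor holes in the Hoechst channel). Background is estimated by
#' grayscale opening with a disc of `background_radius` pixels and
#' subtracted; a moment-preserving (Tsai) threshold computed over
#' within-nucleus pixels then selects the foci. The mask is restricted to
#' the nucleus mask.
#'
#' A separability guard protects uniform interiors: the threshold is kept
#' only when the between-class variance it induces explains at least
#' `min_separability` of the total within-nucleus variance (a unimodal
#' noise histogram tops out near 0.64, well below the default 0.75), so
#' nucleolus-free nuclei yield an empty mask rather than thresholded noise.
#'
#' @param eu Numeric matrix, EU-channel intensities.
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @param background_radius Opening radius in pixels.
#' @param min_separability Minimum between-class variance fraction.
#' @return Logical matrix: nucleolar pixels.
#' @export
segment_nucleoli <- function(eu, nucleus_labels, background_radius = 25,
                             min_separability = 0.75) {
  inside <- nucleus_labels > 0
  if (!any(inside)) return(matrix(FALSE, nrow(eu), ncol(eu)))
  rng <- range(eu)
  scaled <- if (diff(rng) > 0) (eu - rng[1]) / diff(rng) else eu * 0
  img <- EBImage::Image(scaled)
  brush_size <- 2L * as.integer(background_radius) + 1L
  bg <- EBImage::opening(img, EBImage::makeBrush(brush_size, shape = "disc"))
  sub <- pmax(EBImage::imageData(img) - EBImage::imageData(bg), 0)
  vals <- sub[inside]
  thr <- threshold_moments(vals)
  if (is.na(thr)) return(matrix(FALSE, nrow(eu), ncol(eu)))
  above <- vals > thr
  if (!any(above) || all(above)) return(matrix(FALSE, nrow(eu), ncol(eu)))
  p1 <- mean(above)
  between <- p1 * (1 - p1) * (mean(vals[above]) - mean(vals[!above]))^2
  total <- stats::var(vals)
  if (total <= 0 || between / total < min_separability) {
    return(matrix(FALSE, nrow(eu), ncol(eu)))
  }
  (sub > thr) & inside
}

#' Measure nuclei and apply quantification gates
#'
#' For every labeled nucleus: area (pixel count x pixel area), circularity
#' `4*pi*A/P^2` (perimeter from the object contour, clipped at 1 for
#' reporting) and mean nucleoplasmic EU (nucleus minus nucleoli; nucleoli
#' are excluded because their rRNA signal is largely damage-resistant).
#' Gates per the species profile set the flags `too_small`,
#' `too_large_polyploid`, `low_circularity` and (mouse) `low_eu_kupffer_like`;
#' `pass` is their conjunction. The flags are computed independently, so
#' their order is immaterial.
#'
#' @param eu EU-channel matrix.
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @param nucleoli_mask Logical matrix from [segment_nucleoli()].
#' @param pixel_size_um Pixel side length in micrometres.
#' @param profile A [species_profile()].
#' @return Tibble: `label`, `area_um2`, `circularity`,
#'   `nucleoplasm_mean_eu`, the flag columns and `pass`.
#' @export
measure_nuclei <- function(eu, nucleus_labels, nucleoli_mask,
                           pixel_size_um, profile = species_profile("mouse")) {
  stopifnot(all(dim(eu) == dim(nucleus_labels)), pixel_size_um > 0)
  labels <- sort(setdiff(unique(as.integer(nucleus_labels)), 0L))
  if (length(labels) == 0L) {
    abort("no nuclei in mask")
  }
  shp <- EBImage::computeFeatures.shape(nucleus_labels)
  area_px <- shp[, "s.area"]
  perim_px <- shp[, "s.perimeter"]
  area_um2 <- area_px * pixel_size_um^2
  circ <- pmin(4 * pi * area_px / pmax(perim_px, 1)^2, 1)

  nucleoplasm <- (nucleus_labels > 0) & !nucleoli_mask
  mean_eu <- vapply(labels, function(lb) {
    px <- (nucleus_labels == lb) & nucleoplasm
    if (!any(px)) NA_real_ else mean(eu[px])
  }, numeric(1))

  out <- tibble(
    label = labels,
    area_um2 = as.numeric(area_um2[labels]),
    circularity = as.numeric(circ[labels]),
    nucleoplasm_mean_eu = mean_eu,
    too_small = .data$area_um2 < profile$min_area_um2,
    too_large_polyploid = .data$area_um2 > profile$max_area_um2,
    low_circularity = .data$circularity <= profile$min_circularity,
    empty_nucleoplasm = is.na(mean_eu)
  )
  if (!is.na(profile$low_eu_fraction)) {
    size_ok <- !out$too_small & !out$too_large_polyploid &
      !out$low_circularity & !out$empty_nucleoplasm
    ref <- median(out$nucleoplasm_mean_eu[size_ok])
    out$low_eu_kupffer_like <- !is.na(out$nucleoplasm_mean_eu) &
      !is.na(ref) & out$nucleoplasm_mean_eu < profile$low_eu_fraction * ref
  } else {
    out$low_eu_kupffer_like <- FALSE
  }
  out$pass <- !out$too_small & !out$too_large_polyploid &
    !out$low_circularity & !out$low_eu_kupffer_like & !out$empty_nucleoplasm
  out
}

#' Quantify one field of view
#'
#' Runs segmentation, nucleolar exclusion, per-nucleus measurement and the
#' species gates on a two-channel field.
#'
#' @param field List with elements `eu`, `dna` (matrices) and
#'   `pixel_size_um`; [simulate_fields()] produces this shape.
#' @param profile A [species_profile()].
#' @param background_radius Passed to [segment_nucleoli()].
#' @return Tibble of per-nucleus measurements (see [measure_nuclei()]).
#' @export
quantify_field <- function(field, profile = species_profile("mouse"),
                           background_radius = 25) {
  stopifnot(all(dim(field$eu) == dim(field$dna)))
  labels <- segment_nuclei(field$dna)
  nucleoli <- segment_nucleoli(field$eu, labels, background_radius)
  measure_nuclei(field$eu, labels, nucleoli, field$pixel_size_um, profile)
}

#' Per-field summary: median nucleoplasmic EU of passing nuclei
#'
#' @param measurements Tibble from [measure_nuclei()]/[quantify_field()].
#' @return Median nucleoplasmic EU over gate-passing nuclei; `NA` with a
#'   warning when no nucleus passes (the field is excluded downstream).
#' @export
summarize_field <- function(measurements) {
  ok <- measurements$pass
  if (!any(ok)) {
    warn("no gate-passing nuclei in field; excluded")
    return(NA_real_)
  }
  median(measurements$nucleoplasm_mean_eu[ok])
}

#' Normalize per-field summaries to a reference sample
#'
#' Imaging sessions are normalized by dividing each field summary by the
#' mean summary of the session's reference sample (x 100%), so the
#' reference sits at 100%.
#'
#' @param summaries Tibble with columns `sample`, `field_summary`.
#' @param reference Name of the reference sample.
#' @return `summaries` with an added `normalized_pct` column.
#' @export
normalize_cohort <- function(summaries, reference) {
  summaries <- as_tibble(summaries)
  ref_vals <- summaries$field_summary[summaries$sample == reference]
  ref_vals <- ref_vals[!is.na(ref_vals)]
  if (length(ref_vals) == 0L) abort("reference sample absent or all-NA")
  mutate(summaries, normalized_pct = .data$field_summary / mean(ref_vals) * 100)
}
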