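#' Gene-body coverage slope
#'
#' OLS slope of per-bin coverage (RPKM) against 0-based bin index along the
#' gene body, 5'->3' in transcription direction (strand resolved upstream).
#' Genes are length-normalized by binning, so slopes are comparable across
#' genes.
#'
#' @param profile Tibble with columns `bin_index` (0-based, 5'->3') and
#'   `rpkm`, for a single gene/condition; or a bare numeric vector of
#'   per-bin RPKM.
#' @return Slope in RPKM per bin.
#' @examples
#' body_slope(10:0)  # -1
#' @export
body_slope <- function(profile) {
  if (is.numeric(profile)) {
    profile <- tibble(bin_index = seq_along(profile) - 1, rpkm = profile)
  }
  profile <- as_tibble(profile)
  if (!all(c("bin_index", "rpkm") %in% names(profile))) {
    abort("profile needs columns 'bin_index' and 'rpkm'")
  }
  if (nrow(profile) < 3L) abort("need at least 3 bins for a slope")
  if (any(profile$rpkm < 0)) abort("negative RPKM")
  as.numeric(coef(lm(rpkm ~ bin_index, data = profile))[2])
}

#' Tilt: change in gene-body coverage slope after damage
#'
#' `tilt = slope(after) - slope(before)`. A negative tilt means coverage
#' falls off toward the 3' end after damage relative to baseline — the
#' signature of RNA polymerases stalling at transcription-blocking lesions
#' before completing the transcript.
#'
#' @param before,after Profiles for the same gene with identical bin
#'   counts (see [body_slope()]).
#' @return Tilt in RPKM per bin.
#' @examples
#' gene_tilt(rep(5, 11), seq(10, 0))  # -1: 3' deficit after damage
#' @export
gene_tilt <- function(before, after) {
  nb <- if (is.numeric(before)) length(before) else nrow(before)
  na <- if (is.numeric(after)) length(after) else nrow(after)
  if (nb != na) abort("bin-count mismatch between conditions")
  body_slope(after) - body_slope(before)
}

#' Cohort-level tilt
#'
#' Per-gene tilt for all genes present in both conditions, with summary
#' statistics. Input tables are long-format coverage profiles.
#'
#' @param before,after Tibbles with columns `gene_id`, `bin_index`, `rpkm`.
#' @param weights Optional named vector of per-gene weights for the
#'   weighted mean tilt (e.g. expression weights).
#' @return Tibble with `gene_id` and `tilt`; summary statistics (mean,
#'   weighted mean, median, fraction negative) attached as the `"summary"`
#'   attribute and retrievable via [tilt_summary()].
#' @export
cohort_tilt <- function(before, after, weights = NULL) {
  before <- as_tibble(before)
  after <- as_tibble(after)
  genes <- intersect(unique(before$gene_id), unique(after$gene_id))
  if (length(genes) == 0L) abort("no genes shared between conditions")
  per_gene <- map_dbl(genes, function(g) {
    gene_tilt(filter(before, .data$gene_id == g) |> arrange(.data$bin_index),
              filter(after, .data$gene_id == g) |> arrange(.data$bin_index))
  })
  out <- tibble(gene_id = genes, tilt = per_gene)
  w <- if (is.null(weights)) rep(1, length(genes)) else weights[genes]
  attr(out, "summary") <- tibble(
    n_genes = length(genes),
    mean_tilt = mean(per_gene),
    weighted_mean_tilt = sum(w * per_gene) / sum(w),
    median_tilt = median(per_gene),
    fraction_negative = mean(per_gene < 0)
  )
  out
}

#' @rdname cohort_tilt
#' @param tilts Result of [cohort_tilt()].
#' @export
tilt_summary <- function(tilts) {
  s <- attr(tilts, "summary")
  if (is.null(s)) abort("not a cohort_tilt result")
  s
}
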