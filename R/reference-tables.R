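#' Published reference tables
#'
#' Two small tables shipped with the package:
#' * `"fibroblast_dose_errors"` — per-UV-dose model-vs-data error rates for
#'   the human-fibroblast EU dose-response (dose, lesion density and
#'   genome-wide lesion count, absolute/relative error in % and in SEM
#'   multiples).
#' * `"mouse_rates"` — fitted daily unrepaired-lesion rates per mouse
#'   genotype with SD and validation errors.
#'
#' @param which `"fibroblast_dose_errors"` or `"mouse_rates"`.
#' @return A tibble.
#' @examples
#' reference_table("mouse_rates")
#' @export
reference_table <- function(which = c("fibroblast_dose_errors", "mouse_rates")) {
  which <- match.arg(which)
  file <- switch(which,
    fibroblast_dose_errors = "fibroblast_dose_error_table.tsv",
    mouse_rates = "mouse_rate_table.tsv"
  )
  path <- system.file("extdata", file, package = "txstress", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}
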