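# Metric catalogue for DTI/DKI tractometry panels.
#
# Diffusivities (MD/AD/RD) are in um^2/ms (i.e. x 10^-3 mm^2/s); FA and the
# kurtosis metrics (MK/AK/RK) are dimensionless.

#' Diffusion metric identifiers
#'
#' The eleven tractometry metrics analysed by the pipeline: four from the
#' diffusion tensor model (DTI) and seven from the diffusion kurtosis model
#' (DKI).  Metric identifiers are `"<MODEL>_<METRIC>"`, e.g. `"DKI_FA"`.
#'
#' @return Character vector of metric identifiers.
#' @export
wm_metrics <- function() c(dti_metrics(), dki_metrics())

#' @rdname wm_metrics
#' @export
dti_metrics <- function() paste0("DTI_", c("FA", "MD", "AD", "RD"))

#' @rdname wm_metrics
#' @export
dki_metrics <- function() paste0("DKI_", c("FA", "MD", "AD", "RD", "MK", "AK", "RK"))

#' Modality of a metric identifier
#'
#' @param metric character vector of metric identifiers.
#' @return `"dti"` or `"dki"` per element.
#' @export
metric_modality <- function(metric) {
  bad <- !metric %in% wm_metrics()
  if (any(bad)) {
    stop("unknown metric identifier(s): ", paste(metric[bad], collapse = ", "))
  }
  ifelse(startsWith(metric, "DTI_"), "dti", "dki")
}

is_fa_metric <- function(metric) grepl("_FA$", metric)

#' Baseline calibration of the metric catalogue
#'
#' Per-metric baseline centers and scales used by the synthetic cohort
#' generator.  Centers are healthy-adult global white-matter medians and
#' `iqr` the corresponding interquartile ranges as reported for 7T
#' tractometry of 72 bundles; `scale` converts the IQR to a normal-theory
#' standard deviation, `scale = iqr / 1.349`.
#'
#' @return data.frame with columns `metric`, `center`, `iqr`, `scale`.
#' @export
metric_baselines <- function() {
  out <- data.frame(
    metric = wm_metrics(),
    center = c(0.412, 0.779, 1.140, 0.600,
               0.438, 0.948, 1.413, 0.710, 0.966, 0.842, 1.185),
    iqr    = c(0.023, 0.026, 0.032, 0.034,
               0.013, 0.024, 0.046, 0.028, 0.072, 0.033, 0.129),
    stringsAsFactors = FALSE
  )
  out$scale <- out$iqr / 1.349
  out
}
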