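# Median-based skill metrics for model-versus-observation comparison.

#' Median-based percent error
#'
#' `PE = 100 * (median(model) - median(obs)) / median(obs)`, computed over
#' the co-located entries only: positions missing in either field are
#' excluded from both before the medians are taken. The median makes the
#' metric robust to the log-normal tail of chlorophyll fields; even-length
#' medians use the usual midpoint convention.
#'
#' @param model_field,obs_field Numeric vectors of equal length.
#' @return Percent error (%).
#' @export
percent_error <- function(model_field, obs_field) {
  if (length(model_field) != length(obs_field))
    stop("fields must have equal length", call. = FALSE)
  ok <- !is.na(model_field) & !is.na(obs_field)
  if (!any(ok)) stop("no co-located data", call. = FALSE)
  m_obs <- stats::median(obs_field[ok])
  if (m_obs == 0) stop("median of the observations is zero", call. = FALSE)
  100 * (stats::median(model_field[ok]) - m_obs) / m_obs
}

#' Annual percent error
#'
#' Arithmetic mean of the twelve monthly percent errors.
#'
#' @param monthly_pe Numeric vector of exactly 12 non-missing monthly PE
#'   values (%).
#' @return Annual PE (%).
#' @export
annual_pe <- function(monthly_pe) {
  if (length(monthly_pe) != 12L || anyNA(monthly_pe))
    stop("'monthly_pe' must contain 12 non-missing monthly values",
         call. = FALSE)
  mean(monthly_pe)
}

#' Bias in relative community composition
#'
#' Elementwise difference `PFT%_model - PFT%_obs` between two compositions
#' expressed in percent; both inputs must cover the same groups and each
#' sum to approximately 100%, so the differences sum to approximately
#' zero.
#'
#' @param model_frac,obs_frac Named numeric vectors of percent
#'   contributions.
#' @return Named vector of biases in percentage points.
#' @export
pft_fraction_bias <- function(model_frac, obs_frac) {
  if (is.null(names(model_frac)) || is.null(names(obs_frac)) ||
      !setequal(names(model_frac), names(obs_frac)))
    stop("'model_frac' and 'obs_frac' must be named over the same groups",
         call. = FALSE)
  for (v in list(model_frac, obs_frac))
    if (abs(sum(v) - 100) > 0.5)
      stop("compositions must each sum to ~100%", call. = FALSE)
  model_frac - obs_frac[names(model_frac)]
}
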