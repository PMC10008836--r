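# Deseasonalized anomaly machinery: monthly climatology, absolute and
# percent anomalies, rolling mean, Monod-transformed nutrient-limitation
# anomalies, and dominant-group classification joined with compound
# SST-chlorophyll anomalies.

#' Aggregate a (sub-)daily series to monthly means
#'
#' @param time Date vector.
#' @param value Numeric vector; `NA`s are skipped.
#' @return Data frame with columns `time` (first day of month) and `value`.
#' @export
monthly_means <- function(time, value) {
  key <- month_floor(time)
  agg <- tapply(value, key, mean, na.rm = TRUE)
  data.frame(time = as.Date(names(agg)), value = as.numeric(agg))
}

#' Monthly climatology over a baseline period
#'
#' Mean per calendar month over the baseline span, skipping missing
#' values; the reference for deseasonalized anomalies.
#'
#' @param series Data frame with `time` (monthly Dates) and `value`.
#' @param baseline Length-2 Date vector (start, end) delimiting the
#'   baseline; default is the whole series. Must cover at least two full
#'   years (24 monthly records).
#' @return A `monthly_climatology` object: list with `months` (12 means),
#'   `baseline` and `n_per_month`.
#' @export
monthly_climatology <- function(series, baseline = NULL) {
  stopifnot(all(c("time", "value") %in% names(series)))
  if (is.null(baseline)) baseline <- range(series$time)
  baseline <- as.Date(baseline)
  in_base <- series$time >= baseline[1] & series$time <= baseline[2]
  sub <- series[in_base & !is.na(series$value), ]
  if (nrow(sub) < 24)
    stop("baseline must cover at least two full years of monthly data",
         call. = FALSE)
  m <- month_of(sub$time)
  counts <- tabulate(m, 12)
  if (any(counts == 0))
    stop(sprintf("no baseline data for calendar month(s): %s",
                 paste(month.name[counts == 0], collapse = ", ")),
         call. = FALSE)
  means <- vapply(1:12, function(i) mean(sub$value[m == i]), 0)
  structure(list(months = setNames(means, month.abb), baseline = baseline,
                 n_per_month = counts), class = "monthly_climatology")
}

#' Deseasonalized anomalies of a monthly series
#'
#' Absolute anomaly is `value - clim[month]`; percent anomaly is
#' `100 * absolute / clim[month]`, undefined (`NA`) where the
#' climatological mean of that calendar month is zero.
#'
#' @param series Data frame with `time`, `value` at monthly resolution.
#' @param clim A [monthly_climatology()] of the same variable.
#' @return An `anomaly_series` data frame: `time`, `value`, `climatology`,
#'   `absolute`, `percent`.
#' @export
anomaly <- function(series, clim) {
  stopifnot(inherits(clim, "monthly_climatology"))
  cm <- unname(clim$months[month_of(series$time)])
  abs_anom <- series$value - cm
  pct <- ifelse(cm != 0, 100 * abs_anom / cm, NA_real_)
  structure(data.frame(time = series$time, value = series$value,
                       climatology = cm, absolute = abs_anom,
                       percent = pct),
            class = c("anomaly_series", "data.frame"))
}

#' Rolling mean with shrinking edge windows
#'
#' Centered (default) or trailing moving average; at the series edges the
#' window shrinks to the available points, so the output has the same
#' length as the input. Missing values are skipped within each window. For
#' an even centered window of width `w`, the window spans `floor(w/2)`
#' points before through `floor((w-1)/2)` points after each position.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (months for monthly series).
#' @param align `"center"` or `"right"` (trailing).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
rolling_mean <- function(x, window = 6, align = c("center", "right")) {
  align <- match.arg(align)
  if (window < 1) stop("'window' must be >= 1", call. = FALSE)
  n <- length(x)
  if (align == "center") {
    lo <- pmax(seq_len(n) - floor(window / 2), 1)
    hi <- pmin(seq_len(n) + floor((window - 1) / 2), n)
  } else {
    lo <- pmax(seq_len(n) - window + 1L, 1)
    hi <- seq_len(n)
  }
  vapply(seq_len(n), function(i) mean(x[lo[i]:hi[i]], na.rm = TRUE), 0)
}

#' Anomalies of a nutrient growth-limiting term
#'
#' Transforms a nutrient concentration series through the Monod function
#' with the diatom half-saturation for that nutrient (diatoms have the
#' widest limitation-term response), then computes the deseasonalized
#' monthly anomaly of the transformed series. The transform is applied
#' before deseasonalization, so the anomaly refers to the limiting term
#' itself rather than to a transformed concentration anomaly (the two
#' orders differ because the Monod function is nonlinear).
#'
#' @param series Data frame `time`, `value` of monthly nutrient
#'   concentrations (umol/kg, or nmol/kg for iron).
#' @param nutrient `"nitrate"`, `"silicate"` or `"iron"`.
#' @param diatom_params The diatom [pft_params()].
#' @param baseline Optional baseline span passed to
#'   [monthly_climatology()].
#' @return An `anomaly_series` of the dimensionless limitation term.
#' @export
limitation_anomaly <- function(series, nutrient, diatom_params,
                               baseline = NULL) {
  stopifnot(inherits(diatom_params, "pft_params"),
            diatom_params$name == "diatoms")
  k <- switch(nutrient,
              nitrate = diatom_params$k_no3,
              silicate = diatom_params$k_si,
              iron = diatom_params$k_fe,
              stop(sprintf(
                "unknown nutrient '%s'; use nitrate, silicate or iron",
                nutrient), call. = FALSE))
  lim <- data.frame(time = series$time, value = monod(series$value, k))
  anomaly(lim, monthly_climatology(lim, baseline))
}

#' Dominant-group records joined with compound anomalies
#'
#' For each monthly step, finds the group occupying the largest fraction of
#' total chlorophyll biomass (exact ties broken by the fixed group-name
#' order) and joins it with the SST and chlorophyll anomalies at the same
#' time.
#'
#' @param traj A `pft_trajectory`.
#' @param sst_anom,chl_anom `anomaly_series` for SST (absolute, degC) and
#'   chlorophyll; their time axes must be identical to each other.
#' @return A `dominance_records` data frame: `time`, `dominant`,
#'   `sst_anomaly` (degC), `chl_anomaly` (mg m-3).
#' @export
dominance <- function(traj, sst_anom, chl_anom) {
  stopifnot(inherits(traj, "pft_trajectory"))
  if (!identical(as.numeric(sst_anom$time), as.numeric(chl_anom$time)))
    stop("SST and chlorophyll anomaly time axes are misaligned",
         call. = FALSE)
  fr <- biomass_fractions(traj)
  mfr <- apply(fr, 2, function(col) monthly_means(traj$time, col)$value)
  mtime <- monthly_means(traj$time, fr[, 1])$time
  keep <- match(as.numeric(sst_anom$time), as.numeric(mtime))
  if (anyNA(keep))
    stop("anomaly time axis is not aligned with the trajectory months",
         call. = FALSE)
  mfr <- mfr[keep, , drop = FALSE]
  dom <- apply(mfr, 1, function(r) {
    if (anyNA(r)) return(NA_character_)
    sort(PFT_NAMES[r == max(r)])[1]   # exact ties: lexicographically first
  })
  structure(data.frame(time = sst_anom$time, dominant = dom,
                       sst_anomaly = sst_anom$absolute,
                       chl_anomaly = chl_anom$absolute),
            class = c("dominance_records", "data.frame"))
}
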