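# Synthetic seasonal forcing, heatwave scenarios, synthetic chlorophyll
# observations. The generator replaces reanalysis/satellite inputs with a
# minimal sinusoid + AR(1) red-noise structure that still yields a
# nontrivial monthly climatology.

# Region profiles: annual mean, amplitude and peak day-of-year for each
# forcing variable, plus the deep nutrient reservoirs. "subarctic" mimics a
# Gulf-of-Alaska-like seasonal regime (deep winter mixed layer, low winter
# light, strong seasonality); "equatorial" an ENSO-3.4-like regime (weak
# seasonality, strong vertical exchange, iron-poor deep supply).
REGION_PROFILES <- list(
  subarctic = list(
    sst  = list(mean = 9,    amp = 4,    peak = 235),  # degC, late-summer peak
    par0 = list(mean = 22,   amp = 18,   peak = 172),  # mol photons m-2 d-1
    mld  = list(mean = 60,   amp = 40,   peak = 45),   # m, deepest in winter
    kappa = list(mean = 0.015, amp = 0.010, peak = 45), # 1/day
    deep_no3 = 8, deep_si = 6, deep_fe = 0.9,
    noise = list(sst = 0.15, par0 = 0.03, mld = 0.04, kappa = 0.04)
  ),
  equatorial = list(
    sst  = list(mean = 27,   amp = 1.0,  peak = 120),
    par0 = list(mean = 38,   amp = 3,    peak = 80),
    mld  = list(mean = 45,   amp = 10,   peak = 200),
    kappa = list(mean = 0.05, amp = 0.01, peak = 200),
    deep_no3 = 8, deep_si = 8, deep_fe = 0.6,
    noise = list(sst = 0.10, par0 = 0.02, mld = 0.03, kappa = 0.03)
  )
)

new_forcing_series <- function(df) {
  stopifnot(all(c("time", "sst", "par0", "mld", "kappa",
                  "deep_no3", "deep_si", "deep_fe") %in% names(df)))
  if (any(df$mld <= 0)) stop("mld must be > 0", call. = FALSE)
  if (any(df$kappa < 0) || any(df$par0 < 0) ||
      any(df$deep_no3 < 0) || any(df$deep_si < 0) || any(df$deep_fe < 0))
    stop("kappa, par0 and deep reservoirs must be >= 0", call. = FALSE)
  dt <- diff(as.numeric(df$time))
  if (length(dt) && (any(dt <= 0) || any(abs(dt - dt[1]) > 1e-8)))
    stop("time must be strictly increasing with a uniform step", call. = FALSE)
  class(df) <- c("forcing_series", "data.frame")
  df
}

#' Generate seasonal mixed-layer forcing for a region profile
#'
#' Builds a daily (or coarser) time series of sea-surface temperature,
#' surface photosynthetically available radiation (PAR, just below the
#' surface), mixed-layer depth, vertical exchange rate and deep nutrient
#' reservoirs. Each variable follows a sinusoidal annual cycle with
#' profile-specific mean, amplitude and phase, perturbed by a small seeded
#' AR(1) red-noise term; the output is deterministic given the seed.
#'
#' @param years Number of simulated years (>= 1).
#' @param step_days Time step in days, in (0, 31].
#' @param region_profile `"subarctic"` (strong seasonality, deep winter
#'   mixing) or `"equatorial"` (weak seasonality, strong exchange).
#' @param seed Integer seed for the red-noise perturbations.
#' @param start Start date of the series.
#' @return A `forcing_series` data frame with columns `time`, `sst` (degC),
#'   `par0` (mol photons m-2 d-1), `mld` (m), `kappa` (1/day), `deep_no3`
#'   (umol/kg), `deep_si` (umol/kg), `deep_fe` (nmol/kg).
#' @export
#' @examples
#' f <- make_seasonal_forcing(1, 1, "subarctic", seed = 7)
#' range(f$mld)
make_seasonal_forcing <- function(years, step_days = 1,
                                  region_profile = "subarctic", seed = 1,
                                  start = as.Date("2001-01-01")) {
  stop_if_not_scalar(years, "years"); stop_if_not_scalar(step_days, "step_days")
  if (years < 1) stop("'years' must be >= 1", call. = FALSE)
  if (step_days <= 0 || step_days > 31)
    stop("'step_days' must be in (0, 31]", call. = FALSE)
  if (!region_profile %in% names(REGION_PROFILES))
    stop(sprintf("unknown region_profile '%s'; valid profiles: %s",
                 region_profile,
                 paste(names(REGION_PROFILES), collapse = ", ")),
         call. = FALSE)
  prof <- REGION_PROFILES[[region_profile]]
  n <- max(2L, floor(years * 365 / step_days))
  time <- start + (seq_len(n) - 1L) * step_days
  doy <- day_of_year(time)
  seasonal <- function(v) v$mean + v$amp * cos(2 * pi * (doy - v$peak) / 365.25)
  # one RNG substream per variable so a longer series extends, rather than
  # reshuffles, a shorter one generated with the same seed
  noise <- lapply(1:4, function(v)
    with_seed((abs(seed) + v * 1000003L) %% .Machine$integer.max,
              red_noise(n, phi = 0.9)))
  sst <- seasonal(prof$sst) + prof$noise$sst * noise[[1]]
  par0 <- pmax(seasonal(prof$par0) *
                 (1 + prof$noise$par0 * noise[[2]]), 0.1)
  mld <- pmax(seasonal(prof$mld) * (1 + prof$noise$mld * noise[[3]]), 5)
  kappa <- pmax(seasonal(prof$kappa) *
                  (1 + prof$noise$kappa * noise[[4]]), 0)
  new_forcing_series(data.frame(
    time = time, sst = sst, par0 = par0, mld = mld, kappa = kappa,
    deep_no3 = rep(prof$deep_no3, n), deep_si = rep(prof$deep_si, n),
    deep_fe = rep(prof$deep_fe, n)))
}

#' Specify a heatwave scenario
#'
#' Encodes a multi-month warm anomaly with reduced wind-driven nutrient
#' supply: within the event window (with linear on/off ramps) SST is raised
#' by `sst_amplitude`, the vertical nutrient supply `kappa * deep_X` is
#' scaled by the per-nutrient supply factors (implemented on the deep
#' reservoirs so surface drawdown emerges dynamically), and the mixed-layer
#' depth is scaled by `mld_factor`.
#'
#' @param kind `"baseline"` (identity), `"blob"` (silicate-starved
#'   subarctic event) or `"elnino"` (nitrate-starved equatorial event).
#' @param onset Date of event onset.
#' @param duration_months Event duration in months (> 0).
#' @param sst_amplitude Peak SST anomaly, degC.
#' @param supply_factor_no3,supply_factor_si,supply_factor_fe Multipliers
#'   in \[0, 1\] applied to the respective deep supply inside the window.
#' @param mld_factor Mixed-layer depth multiplier (> 0) inside the window.
#' @param ramp_months Length of each linear on/off ramp, months;
#'   `duration_months` must be at least `2 * ramp_months`.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(kind = c("baseline", "blob", "elnino"),
                          onset = as.Date("2003-05-01"),
                          duration_months = 8, sst_amplitude = 0,
                          supply_factor_no3 = 1, supply_factor_si = 1,
                          supply_factor_fe = 1, mld_factor = 1,
                          ramp_months = 1) {
  kind <- match.arg(kind)
  if (duration_months <= 0) stop("'duration_months' must be > 0", call. = FALSE)
  for (v in c("supply_factor_no3", "supply_factor_si", "supply_factor_fe")) {
    val <- get(v)
    if (val < 0 || val > 1)
      stop(sprintf("'%s' must be in [0, 1]", v), call. = FALSE)
  }
  if (mld_factor <= 0) stop("'mld_factor' must be > 0", call. = FALSE)
  if (ramp_months < 0 || 2 * ramp_months > duration_months)
    stop("'ramp_months' must satisfy 0 <= 2*ramp <= duration", call. = FALSE)
  structure(list(kind = kind, onset = as.Date(onset),
                 duration_months = duration_months,
                 sst_amplitude = sst_amplitude,
                 supply_factor_no3 = supply_factor_no3,
                 supply_factor_si = supply_factor_si,
                 supply_factor_fe = supply_factor_fe,
                 mld_factor = mld_factor, ramp_months = ramp_months),
            class = "scenario_spec")
}

# trapezoidal event weight in [0, 1]: linear ramps of `ramp` months at each
# end of the [onset, onset + duration] window, plateau of 1 between them
scenario_weight <- function(time, scenario) {
  t0 <- as.numeric(scenario$onset)
  t1 <- t0 + scenario$duration_months * 30.44
  r <- scenario$ramp_months * 30.44
  tt <- as.numeric(time)
  w <- rep(0, length(tt))
  inside <- tt >= t0 & tt <= t1
  w[inside] <- 1
  if (r > 0) {
    up <- inside & tt < t0 + r
    dn <- inside & tt > t1 - r
    w[up] <- (tt[up] - t0) / r
    w[dn] <- (t1 - tt[dn]) / r
  }
  w
}

#' Superimpose a heatwave scenario on a forcing series
#'
#' Outside the event window the forcing is returned unchanged; the
#' `"baseline"` scenario is the identity everywhere.
#'
#' @param forcing A [make_seasonal_forcing()] output.
#' @param scenario A [scenario_spec()].
#' @return A modified `forcing_series`.
#' @export
apply_scenario <- function(forcing, scenario) {
  stopifnot(inherits(forcing, "forcing_series"),
            inherits(scenario, "scenario_spec"))
  if (scenario$kind == "baseline") return(forcing)
  t0 <- scenario$onset
  t1 <- t0 + scenario$duration_months * 30.44
  if (t0 < min(forcing$time) || as.numeric(t1) > as.numeric(max(forcing$time)))
    stop("scenario window falls outside the forcing time span", call. = FALSE)
  w <- scenario_weight(forcing$time, scenario)
  out <- forcing
  out$sst <- forcing$sst + w * scenario$sst_amplitude
  out$mld <- forcing$mld * (1 + w * (scenario$mld_factor - 1))
  out$deep_no3 <- forcing$deep_no3 * (1 + w * (scenario$supply_factor_no3 - 1))
  out$deep_si  <- forcing$deep_si  * (1 + w * (scenario$supply_factor_si - 1))
  out$deep_fe  <- forcing$deep_fe  * (1 + w * (scenario$supply_factor_fe - 1))
  new_forcing_series(out)
}

#' Generate noisy, gappy synthetic chlorophyll observations
#'
#' Emulates a satellite ocean-color record: multiplicative Gaussian noise
#' `obs = truth * (1 + eps)` clipped at zero, and a seeded Bernoulli mask
#' that removes approximately `gap_fraction` of the points (set to `NA`).
#'
#' @param time Observation timestamps (Date).
#' @param truth_chl True chlorophyll, mg m-3, non-negative.
#' @param noise_sd_rel Relative noise standard deviation (>= 0).
#' @param gap_fraction Fraction of missing points, in \[0, 1).
#' @param seed Integer seed; identical arguments give identical output.
#' @return An `obs_series` data frame with columns `time`, `chl_obs`.
#' @export
make_synthetic_obs <- function(time, truth_chl, noise_sd_rel = 0.1,
                               gap_fraction = 0, seed = 1) {
  if (length(time) != length(truth_chl))
    stop("'time' and 'truth_chl' lengths differ", call. = FALSE)
  if (any(truth_chl < 0, na.rm = TRUE))
    stop("'truth_chl' must be >= 0", call. = FALSE)
  if (noise_sd_rel < 0) stop("'noise_sd_rel' must be >= 0", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("'gap_fraction' must be in [0, 1)", call. = FALSE)
  n <- length(time)
  obs <- with_seed(seed, {
    eps <- rnorm(n, sd = noise_sd_rel)
    x <- pmax(truth_chl * (1 + eps), 0)
    x[runif(n) < gap_fraction] <- NA_real_
    x
  })
  structure(data.frame(time = as.Date(time), chl_obs = obs),
            noise_sd_rel = noise_sd_rel, gap_fraction = gap_fraction,
            seed = seed, class = c("obs_series", "data.frame"))
}
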