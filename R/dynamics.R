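# Forward six-group mixed-layer box model: temperature-scaled Monod/Liebig
# growth, Stokes-law sinking, Ivlev grazing applied as a uniform specific
# rate, nutrient drawdown with partial recycling to ammonium/iron, and
# vertical exchange with deep reservoirs.

#' Temperature-dependent growth multiplier
#'
#' `R(T) = 1.066^(T - 20)`, normalized to 1 at 20 degrees C (an Eppley-type
#' exponential with Q10 of about 1.9).
#'
#' @param t Temperature, degrees C. Vectorized.
#' @return Dimensionless multiplier.
#' @export
temperature_factor <- function(t) 1.066^(t - 20)

#' Monod saturating uptake function
#'
#' `conc / (k + conc)`; 0.5 at the half-saturation concentration `k`.
#'
#' @param conc Concentration (>= 0).
#' @param k Half-saturation, same units (> 0).
#' @return Dimensionless value in \[0, 1).
#' @export
monod <- function(conc, k) {
  if (any(conc < 0)) stop("'conc' must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("'k' must be > 0", call. = FALSE)
  conc / (k + conc)
}

#' Model state of the mixed-layer box
#'
#' Chlorophyll per functional type plus the four dissolved nutrient pools
#' at one time.
#'
#' @param time A Date.
#' @param chl Named numeric of six chlorophyll concentrations, mg m-3.
#' @param no3 Nitrate, umol/kg.
#' @param nh4 Ammonium, umol/kg.
#' @param si Silicate, umol/kg.
#' @param fe Dissolved iron, nmol/kg.
#' @return A `model_state` object.
#' @export
model_state <- function(time, chl, no3, nh4, si, fe) {
  if (length(chl) != 6L || !setequal(names(chl), PFT_NAMES))
    stop("'chl' must be a named vector over the six group names",
         call. = FALSE)
  chl <- chl[PFT_NAMES]
  if (any(chl < 0) || no3 < 0 || nh4 < 0 || si < 0 || fe < 0)
    stop("all concentrations must be >= 0", call. = FALSE)
  structure(list(time = as.Date(time), chl = chl, no3 = no3, nh4 = nh4,
                 si = si, fe = fe), class = "model_state")
}

#' Default initial state
#'
#' Every group starts at 0.5 mg Chl m-3 and ammonium at 0.5 umol/kg;
#' nitrate, silicate and iron start at their deep-reservoir values.
#'
#' @param forcing A `forcing_series`; its first row supplies the time and
#'   nutrient reservoirs.
#' @return A `model_state`.
#' @export
default_init <- function(forcing) {
  stopifnot(inherits(forcing, "forcing_series"))
  model_state(forcing$time[1],
              setNames(rep(0.5, 6), PFT_NAMES),
              no3 = forcing$deep_no3[1], nh4 = 0.5,
              si = forcing$deep_si[1], fe = forcing$deep_fe[1])
}

#' Liebig-minimum nutrient limitation for one group
#'
#' Computes the Monod terms for nitrogen (NO3 + NH4, against `k_no3`), iron
#' (against `k_fe`) and, for diatoms only, silicate (against `k_si`), and
#' returns the minimum together with the name of the binding nutrient.
#' Non-diatoms ignore silicate entirely. Exact ties are broken in the fixed
#' order N, Fe, Si.
#'
#' @param state A [model_state()].
#' @param pft A [pft_params()].
#' @return List with `f_nut` (dimensionless) and `binding`
#'   (`"N"`, `"Fe"` or `"Si"`).
#' @export
nutrient_limitation <- function(state, pft) {
  stopifnot(inherits(state, "model_state"), inherits(pft, "pft_params"))
  terms <- c(N = monod(state$no3 + state$nh4, pft$k_no3),
             Fe = monod(state$fe, pft$k_fe))
  if (pft$name == "diatoms")
    terms <- c(terms, Si = monod(state$si, pft$k_si))
  i <- which.min(terms)   # which.min takes the first minimum: N, Fe, Si order
  list(f_nut = unname(terms[i]), binding = names(terms)[i])
}

#' Realized growth rate of one group
#'
#' `mu = mu_max * min(f_nut, f_E) * R(T)`: Liebig minimum between the
#' nutrient- and light-limiting terms, scaled by the temperature factor.
#'
#' @param pft A [pft_params()].
#' @param state A [model_state()].
#' @param e_ml Mean mixed-layer PAR.
#' @param t Temperature, degrees C.
#' @return Growth rate, 1/day.
#' @export
growth_rate <- function(pft, state, e_ml, t) {
  f_nut <- nutrient_limitation(state, pft)$f_nut
  f_e <- light_limitation(e_ml, pft$k_e)
  pft$mu_max * min(f_nut, f_e) * temperature_factor(t)
}

#' Temperature-adjusted sinking rate
#'
#' `w = w0 * (0.451 + 0.0178 * T)`: the reference speed `w0` (defined at
#' 31 degrees C, where the multiplier is ~1) scaled by a linear
#' temperature-viscosity factor from Stokes law.
#'
#' @param w0 Reference sinking speed, m/day (>= 0).
#' @param t Temperature, degrees C.
#' @return Sinking speed, m/day.
#' @export
sinking_rate <- function(w0, t) {
  if (any(w0 < 0)) stop("'w0' must be >= 0", call. = FALSE)
  w0 * (0.451 + 0.0178 * t)
}

#' Ivlev grazing rate on total chlorophyll
#'
#' `gamma = gamma_m * R_h(T) * (1 - exp(-lambda * total_chl))` with the
#' grazing temperature dependence `R_h = 0.06 * exp(0.1 T) + 0.7`. The
#' returned value is a specific loss rate (1/day) applied identically to
#' every group, i.e. grazing removes biomass proportionally to relative
#' abundance and leaves community composition unchanged.
#'
#' @param total_chl Total chlorophyll, mg m-3 (>= 0).
#' @param t Temperature, degrees C.
#' @param params A [community_params()].
#' @return Specific grazing rate, 1/day.
#' @export
grazing_rate <- function(total_chl, t, params) {
  if (any(total_chl < 0)) stop("'total_chl' must be >= 0", call. = FALSE)
  rh <- 0.06 * exp(0.1 * t) + 0.7
  params$gamma_m * rh * (1 - exp(-params$ivlev_lambda * total_chl))
}

# One evaluation of all rate terms at a state + instantaneous forcing.
# Vectorized over the six groups; used by both tendencies() and the
# integrator hot loop. `pv` is param_vectors(params).
rates_at <- function(chl, no3, nh4, si, fe, sst, par0, mld, pv, params) {
  chl_tot <- sum(chl)
  kd490 <- kd490_from_chl(chl_tot)
  kd_par <- kdpar_from_kd490(kd490)
  e_ml <- mixed_layer_mean_par(par0, kd_par, mld)
  f_e <- e_ml / (pv$k_e + e_ml)
  n_tot <- no3 + nh4
  f_n <- n_tot / (pv$k_no3 + n_tot)
  f_fe <- fe / (pv$k_fe + fe)
  f_si <- ifelse(is.finite(pv$k_si), si / (pv$k_si + si), 1)
  f_nut <- pmin(f_n, f_fe, f_si)
  # binding label, ties broken in N, Fe, Si order
  binding <- rep("N", 6L)
  binding[f_fe < f_n] <- "Fe"
  binding[f_si < pmin(f_n, f_fe)] <- "Si"
  r_t <- temperature_factor(sst)
  mu <- pv$mu_max * pmin(f_nut, f_e) * r_t
  gamma <- grazing_rate(chl_tot, sst, params)
  w <- sinking_rate(pv$w0, sst)
  list(chl_tot = chl_tot, kd490 = kd490, kd_par = kd_par, e_ml = e_ml,
       f_e = f_e, f_nut = f_nut, binding = binding, r_t = r_t, mu = mu,
       gamma = gamma, w = w)
}

#' Instantaneous tendencies of the box-model state
#'
#' Assembles growth, grazing, sinking, nutrient uptake, recycling and
#' vertical exchange into time derivatives of every state variable:
#' `dP_i/dt = (mu_i - gamma - w_i/H) P_i`; nitrate and silicate and iron
#' relax toward the deep reservoirs at rate `kappa` while being drawn down
#' by uptake (nitrogen uptake split between NO3 and NH4 in proportion to
#' the pool sizes); a fraction `recycle_frac` of grazed nitrogen and iron
#' is returned to the ammonium and iron pools.
#'
#' @param state A [model_state()].
#' @param forcing_at_t One-row slice of a `forcing_series` (or a list with
#'   fields `sst`, `par0`, `mld`, `kappa`, `deep_no3`, `deep_si`,
#'   `deep_fe`).
#' @param params A [community_params()].
#' @return Named list of rates: `chl` (length 6), `no3`, `nh4`, `si`, `fe`,
#'   plus the diagnostic rate terms.
#' @export
tendencies <- function(state, forcing_at_t, params) {
  stopifnot(inherits(state, "model_state"),
            inherits(params, "community_params"))
  f <- forcing_at_t
  if (f$mld <= 0) stop("mixed-layer depth must be > 0", call. = FALSE)
  pv <- param_vectors(params)
  tendencies_raw(state$chl, state$no3, state$nh4, state$si, state$fe,
                 f$sst, f$par0, f$mld, f$kappa,
                 f$deep_no3, f$deep_si, f$deep_fe, pv, params)
}

tendencies_raw <- function(chl, no3, nh4, si, fe, sst, par0, mld, kappa,
                           deep_no3, deep_si, deep_fe, pv, params) {
  r <- rates_at(chl, no3, nh4, si, fe, sst, par0, mld, pv, params)
  dchl <- (r$mu - r$gamma - r$w / mld) * chl
  uptake_n <- sum(r$mu * chl * pv$r_n_chl)
  n_tot <- no3 + nh4
  phi_no3 <- if (n_tot > 0) no3 / n_tot else 0
  phi_nh4 <- if (n_tot > 0) nh4 / n_tot else 0
  uptake_si <- sum(r$mu * chl * pv$r_si_chl)   # nonzero for diatoms only
  uptake_fe <- sum(r$mu * chl * pv$r_fe_chl)
  eps <- params$recycle_frac
  grazed_n <- r$gamma * sum(chl * pv$r_n_chl)
  grazed_fe <- r$gamma * sum(chl * pv$r_fe_chl)
  list(chl = dchl,
       no3 = kappa * (deep_no3 - no3) - uptake_n * phi_no3,
       nh4 = eps * grazed_n - uptake_n * phi_nh4,
       si = kappa * (deep_si - si) - uptake_si,
       fe = kappa * (deep_fe - fe) - uptake_fe + eps * grazed_fe,
       diag = r)
}

#' Run the box model forward in time
#'
#' Explicit fixed-step integration of [tendencies()] with positivity
#' clipping at zero, recording the full diagnostic suite (per-group growth
#' rate, limitation terms, binding nutrient, light field, grazing and
#' sinking rates) at every step. The default method is classical
#' fourth-order Runge-Kutta, which keeps the daily-step solution within a
#' fraction of a percent of a fine-step reference even through the fast
#' bloom and drawdown transients; first-order Euler is available for
#' comparison but needs a much smaller step for the same accuracy. Forcing
#' is interpolated linearly to sub-daily steps. Deterministic.
#'
#' @param forcing A `forcing_series`.
#' @param params A [community_params()]; defaults to the shipped set.
#' @param init A [model_state()]; defaults to [default_init()].
#' @param dt Time step in days; must not exceed the forcing step.
#' @param method `"rk4"` (default) or `"euler"`.
#' @return A `pft_trajectory` object: list with `time`, `chl`
#'   (steps x 6 matrix), `no3`, `nh4`, `si`, `fe`, `chl_tot`, and a
#'   `diagnostics` list of aligned matrices/vectors (`mu`, `f_nut`, `f_e`,
#'   `binding`, `r_t`, `gamma`, `w`, `kd490`, `kd_par`, `e_ml`,
#'   `assimilated`).
#' @export
#' @examples
#' f <- make_seasonal_forcing(2, 1, "subarctic", seed = 1)
#' traj <- run_simulation(f, dt = 1)
#' summary(traj)
run_simulation <- function(forcing, params = default_params(),
                           init = default_init(forcing), dt = 1,
                           method = c("rk4", "euler")) {
  run_core(forcing, params, init, dt, obs = NULL, cfg = NULL,
           method = match.arg(method))
}

# Shared integrator for the free and assimilated runs. When `obs`/`cfg` are
# given, an assimilation update is applied after the dynamics step at every
# cadence tick that has a non-missing observation.
run_core <- function(forcing, params, init, dt, obs, cfg,
                     method = "rk4") {
  stopifnot(inherits(forcing, "forcing_series"),
            inherits(params, "community_params"),
            inherits(init, "model_state"))
  if (anyNA(forcing[c("sst", "par0", "mld", "kappa",
                      "deep_no3", "deep_si", "deep_fe")])) {
    bad <- which(rowSums(is.na(forcing[c("sst", "par0", "mld", "kappa",
                                         "deep_no3", "deep_si",
                                         "deep_fe")])) > 0)[1]
    stop(sprintf("NaN in forcing at %s", forcing$time[bad]), call. = FALSE)
  }
  f_step <- as.numeric(forcing$time[2] - forcing$time[1])
  if (dt > f_step + 1e-9)
    stop("'dt' must not exceed the forcing time step", call. = FALSE)
  pv <- param_vectors(params)
  t_rel <- as.numeric(forcing$time - forcing$time[1])
  t_end <- t_rel[length(t_rel)]
  nt <- floor(t_end / dt + 1e-9) + 1L
  tt <- (seq_len(nt) - 1L) * dt
  interp <- function(col) stats::approx(t_rel, forcing[[col]], tt,
                                        rule = 2)$y
  sst <- interp("sst"); par0 <- interp("par0"); mld <- interp("mld")
  kappa <- interp("kappa"); dno3 <- interp("deep_no3")
  dsi <- interp("deep_si"); dfe <- interp("deep_fe")

  assim_due <- rep(FALSE, nt)
  obs_at <- rep(NA_real_, nt)
  if (!is.null(obs)) {
    m <- match(as.numeric(forcing$time[1] + tt), as.numeric(obs$time))
    obs_at[!is.na(m)] <- obs$chl_obs[m[!is.na(m)]]
    cad <- (tt %% cfg$cadence) < 1e-9
    assim_due <- cad & !is.na(obs_at)
  }

  chl <- matrix(NA_real_, nt, 6, dimnames = list(NULL, PFT_NAMES))
  no3 <- nh4 <- si <- fe <- numeric(nt)
  mu <- f_nut <- f_e <- w <- matrix(NA_real_, nt, 6,
                                    dimnames = list(NULL, PFT_NAMES))
  binding <- matrix(NA_character_, nt, 6, dimnames = list(NULL, PFT_NAMES))
  gamma <- r_t <- kd490 <- kd_par <- e_ml <- numeric(nt)
  assim_flag <- logical(nt)

  p_chl <- init$chl[PFT_NAMES]
  p_no3 <- init$no3; p_nh4 <- init$nh4; p_si <- init$si; p_fe <- init$fe

  for (k in seq_len(nt)) {
    if (assim_due[k]) {
      upd <- assimilate_raw(p_chl, p_no3, p_nh4, p_si, p_fe,
                            obs_at[k], cfg, pv, params)
      p_chl <- upd$chl; p_no3 <- upd$no3; p_nh4 <- upd$nh4
      p_si <- upd$si; p_fe <- upd$fe
      assim_flag[k] <- TRUE
    }
    d <- tendencies_raw(p_chl, p_no3, p_nh4, p_si, p_fe,
                        sst[k], par0[k], mld[k], kappa[k],
                        dno3[k], dsi[k], dfe[k], pv, params)
    chl[k, ] <- p_chl; no3[k] <- p_no3; nh4[k] <- p_nh4
    si[k] <- p_si; fe[k] <- p_fe
    mu[k, ] <- d$diag$mu; f_nut[k, ] <- d$diag$f_nut; f_e[k, ] <- d$diag$f_e
    binding[k, ] <- d$diag$binding; w[k, ] <- d$diag$w
    gamma[k] <- d$diag$gamma; r_t[k] <- d$diag$r_t
    kd490[k] <- d$diag$kd490; kd_par[k] <- d$diag$kd_par
    e_ml[k] <- d$diag$e_ml
    if (k < nt) {
      if (method == "euler") {
        p_chl <- pmax(p_chl + dt * d$chl, 0)
        p_no3 <- max(p_no3 + dt * d$no3, 0)
        p_nh4 <- max(p_nh4 + dt * d$nh4, 0)
        p_si <- max(p_si + dt * d$si, 0)
        p_fe <- max(p_fe + dt * d$fe, 0)
      } else {
        # classical RK4; forcing at the half step is the mean of the two
        # bracketing (linearly interpolated) samples, stage states are
        # clipped at zero before rate evaluation
        fmid <- function(v) 0.5 * (v[k] + v[k + 1])
        eval_d <- function(st, sstv, parv, mldv, kapv, n3, s2, f2)
          tendencies_raw(pmax(st$chl, 0), max(st$no3, 0), max(st$nh4, 0),
                         max(st$si, 0), max(st$fe, 0),
                         sstv, parv, mldv, kapv, n3, s2, f2, pv, params)
        st0 <- list(chl = p_chl, no3 = p_no3, nh4 = p_nh4,
                    si = p_si, fe = p_fe)
        add <- function(st, d, h) list(chl = st$chl + h * d$chl,
                                       no3 = st$no3 + h * d$no3,
                                       nh4 = st$nh4 + h * d$nh4,
                                       si = st$si + h * d$si,
                                       fe = st$fe + h * d$fe)
        k1 <- d
        k2 <- eval_d(add(st0, k1, dt / 2), fmid(sst), fmid(par0),
                     fmid(mld), fmid(kappa), fmid(dno3), fmid(dsi),
                     fmid(dfe))
        k3 <- eval_d(add(st0, k2, dt / 2), fmid(sst), fmid(par0),
                     fmid(mld), fmid(kappa), fmid(dno3), fmid(dsi),
                     fmid(dfe))
        k4 <- eval_d(add(st0, k3, dt), sst[k + 1], par0[k + 1],
                     mld[k + 1], kappa[k + 1], dno3[k + 1], dsi[k + 1],
                     dfe[k + 1])
        comb <- function(f) (k1[[f]] + 2 * k2[[f]] + 2 * k3[[f]] +
                               k4[[f]]) / 6
        p_chl <- pmax(p_chl + dt * comb("chl"), 0)
        p_no3 <- max(p_no3 + dt * comb("no3"), 0)
        p_nh4 <- max(p_nh4 + dt * comb("nh4"), 0)
        p_si <- max(p_si + dt * comb("si"), 0)
        p_fe <- max(p_fe + dt * comb("fe"), 0)
      }
    }
  }
  structure(list(time = forcing$time[1] + tt, chl = chl, no3 = no3,
                 nh4 = nh4, si = si, fe = fe, chl_tot = rowSums(chl),
                 dt = dt,
                 diagnostics = list(mu = mu, f_nut = f_nut, f_e = f_e,
                                    binding = binding, gamma = gamma,
                                    r_t = r_t, w = w, kd490 = kd490,
                                    kd_par = kd_par, e_ml = e_ml,
                                    assimilated = assim_flag)),
            class = "pft_trajectory")
}

#' Biomass fraction of each group along a trajectory
#'
#' `fraction_i = chl_i / chl_tot` per step; rows sum to 1 wherever total
#' chlorophyll is positive, and are `NA` where it is zero.
#'
#' @param traj A `pft_trajectory`.
#' @return Matrix of fractions, steps x 6.
#' @export
biomass_fractions <- function(traj) {
  stopifnot(inherits(traj, "pft_trajectory"))
  fr <- traj$chl / traj$chl_tot
  fr[traj$chl_tot == 0, ] <- NA_real_
  fr
}
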