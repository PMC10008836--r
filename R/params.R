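#' Physiological parameters for one phytoplankton functional type
#'
#' Constructs and validates the per-group constants used by the growth,
#' sinking and nutrient-uptake terms of the box model. Silicate fields
#' (`k_si`, `r_si_chl`) are required for diatoms and must be absent (`NA`)
#' for every other group, which do not take up silicate.
#'
#' @param name Group name; one of `"diatoms"`, `"coccolithophores"`,
#'   `"chlorophytes"`, `"dinoflagellates"`, `"cyanobacteria"`,
#'   `"phaeocystis"`.
#' @param mu_max Maximum growth rate at 20 degrees C (1/day).
#' @param k_no3 Half-saturation concentration for nitrogen uptake
#'   (NO3 + NH4), umol/kg.
#' @param k_fe Half-saturation for dissolved iron, nmol/kg.
#' @param k_si Half-saturation for silicate, umol/kg (diatoms only).
#' @param k_e Half-saturation irradiance for the light-limitation term,
#'   mol photons m-2 d-1.
#' @param w0 Reference sinking speed, m/day, defined at 31 degrees C.
#' @param r_n_chl Nitrogen-to-chlorophyll uptake ratio, umol/kg per
#'   mg Chl m-3.
#' @param r_si_chl Silicate-to-chlorophyll ratio (diatoms only).
#' @param r_fe_chl Iron-to-chlorophyll ratio, nmol/kg per mg Chl m-3.
#' @return A `pft_params` object (named list).
#' @export
pft_params <- function(name, mu_max, k_no3, k_fe, k_si = NA_real_, k_e, w0,
                       r_n_chl, r_si_chl = NA_real_, r_fe_chl) {
  name <- match.arg(name, PFT_NAMES)
  for (v in c("mu_max", "k_no3", "k_fe", "k_e", "r_n_chl", "r_fe_chl"))
    if (get(v) <= 0) stop(sprintf("'%s' must be > 0", v), call. = FALSE)
  if (w0 < 0) stop("'w0' must be >= 0", call. = FALSE)
  if (name == "diatoms") {
    if (is.na(k_si) || is.na(r_si_chl) || k_si <= 0 || r_si_chl <= 0)
      stop("diatoms require positive 'k_si' and 'r_si_chl'", call. = FALSE)
  } else if (!is.na(k_si) || !is.na(r_si_chl)) {
    stop("silicate parameters are only meaningful for diatoms", call. = FALSE)
  }
  structure(list(name = name, mu_max = mu_max, k_no3 = k_no3, k_fe = k_fe,
                 k_si = k_si, k_e = k_e, w0 = w0, r_n_chl = r_n_chl,
                 r_si_chl = r_si_chl, r_fe_chl = r_fe_chl),
            class = "pft_params")
}

#' Community-level parameters for the six-group box model
#'
#' Bundles the six [pft_params()] sets with the shared Ivlev grazing
#' constants and the recycling fraction. Grazing acts on total chlorophyll
#' and is applied to each group as the same specific rate, so it does not
#' alter community composition.
#'
#' @param pfts List of exactly six `pft_params`, one per group name.
#' @param gamma_m Maximum grazing rate at 20 degrees C, 1/day.
#' @param ivlev_lambda Ivlev saturation constant, (mg Chl m-3)^-1.
#' @param recycle_frac Fraction of grazed nitrogen/iron returned to the
#'   ammonium/iron pools (the rest is exported), in \[0, 1\].
#' @param background_fractions Named fractions used to reseed the community
#'   if assimilation meets a zero-biomass state; must sum to 1.
#' @return A `community_params` object.
#' @export
community_params <- function(pfts, gamma_m = 0.35, ivlev_lambda = 1.0,
                             recycle_frac = 0.75,
                             background_fractions = NULL) {
  if (length(pfts) != 6L || !all(vapply(pfts, inherits, TRUE, "pft_params")))
    stop("'pfts' must be a list of six pft_params objects", call. = FALSE)
  nms <- vapply(pfts, `[[`, "", "name")
  if (!setequal(nms, PFT_NAMES) || anyDuplicated(nms))
    stop("'pfts' must contain each of the six group names exactly once",
         call. = FALSE)
  if (gamma_m < 0) stop("'gamma_m' must be >= 0", call. = FALSE)
  if (ivlev_lambda <= 0) stop("'ivlev_lambda' must be > 0", call. = FALSE)
  if (recycle_frac < 0 || recycle_frac > 1)
    stop("'recycle_frac' must be in [0, 1]", call. = FALSE)
  pfts <- pfts[match(PFT_NAMES, nms)]
  names(pfts) <- PFT_NAMES
  if (is.null(background_fractions))
    background_fractions <- setNames(rep(1 / 6, 6), PFT_NAMES)
  background_fractions <- background_fractions[PFT_NAMES]
  if (anyNA(background_fractions) ||
      abs(sum(background_fractions) - 1) > 1e-6)
    stop("'background_fractions' must cover all six groups and sum to 1",
         call. = FALSE)
  structure(list(pfts = pfts, gamma_m = gamma_m,
                 ivlev_lambda = ivlev_lambda, recycle_frac = recycle_frac,
                 background_fractions = background_fractions),
            class = "community_params")
}

#' Read model parameters from a YAML configuration file
#'
#' The file mirrors the [pft_params()] / [community_params()] field names,
#' with units documented in comments; see
#' `system.file("extdata", "default_params.yaml", package = "pftbox")` for
#' the shipped defaults and their rationale.
#'
#' @param path Path to a YAML file; defaults to the shipped configuration.
#' @return A `community_params` object.
#' @export
read_params_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_params.yaml", package = "pftbox")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pfts) || is.null(cfg$community))
    stop("config must contain 'pfts' and 'community' sections", call. = FALSE)
  pfts <- lapply(names(cfg$pfts), function(nm) {
    do.call(pft_params, c(list(name = nm), cfg$pfts[[nm]]))
  })
  bg <- cfg$community$background_fractions
  if (!is.null(bg)) bg <- unlist(bg)
  community_params(pfts,
                   gamma_m = cfg$community$gamma_m,
                   ivlev_lambda = cfg$community$ivlev_lambda,
                   recycle_frac = cfg$community$recycle_frac,
                   background_fractions = bg)
}

#' Default community parameters
#'
#' Convenience wrapper returning the shipped parameter set.
#' @return A `community_params` object.
#' @export
default_params <- function() read_params_config()

# Collapse a community_params into parallel numeric vectors for the
# integrator hot loop. Non-diatom k_si is +Inf so the silicate Monod term is
# 1 (ignored); r_si_chl is 0 so they take up no silicate.
param_vectors <- function(params) {
  p <- params$pfts
  g <- function(f) vapply(p, `[[`, 0, f)
  list(name = PFT_NAMES, mu_max = g("mu_max"), k_no3 = g("k_no3"),
       k_fe = g("k_fe"),
       k_si = ifelse(is.na(g("k_si")), Inf, g("k_si")),
       k_e = g("k_e"), w0 = g("w0"), r_n_chl = g("r_n_chl"),
       r_si_chl = ifelse(is.na(g("r_si_chl")), 0, g("r_si_chl")),
       r_fe_chl = g("r_fe_chl"))
}

#' @export
print.community_params <- function(x, ...) {
  cat("Community parameters: 6 phytoplankton functional types\n")
  v <- param_vectors(x)
  tab <- data.frame(mu_max = v$mu_max, k_no3 = v$k_no3, k_fe = v$k_fe,
                    k_si = v$k_si, k_e = v$k_e, w0 = v$w0,
                    row.names = v$name)
  print(tab, ...)
  cat(sprintf("gamma_m = %.3g /d, Ivlev lambda = %.3g, recycle_frac = %.2f\n",
              x$gamma_m, x$ivlev_lambda, x$recycle_frac))
  invisible(x)
}
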