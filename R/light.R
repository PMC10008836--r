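# Mixed-layer light field, reconstructed offline from surface PAR and the
# mean mixed-layer chlorophyll concentration: chlorophyll sets the diffuse
# attenuation coefficient at 490 nm (Morel-type empirical relation), Kd490
# maps to a broadband PAR attenuation coefficient, Beer-Lambert decay is
# averaged analytically over the mixed layer, and a Monod form converts the
# mean light level to a growth-limiting term.

#' Diffuse attenuation coefficient at 490 nm from chlorophyll
#'
#' Kd490 = 0.0166 + 0.0773 * Chl^0.6715 (m-1), monotone increasing in
#' chlorophyll; the intercept 0.0166 m-1 is the clear-water limit.
#'
#' @param chl Chlorophyll concentration, mg m-3 (>= 0). Vectorized.
#' @return Kd490 in m-1.
#' @export
kd490_from_chl <- function(chl) {
  if (any(chl < 0, na.rm = TRUE)) stop("'chl' must be >= 0", call. = FALSE)
  0.0166 + 0.0773 * chl^0.6715
}

#' Broadband PAR attenuation coefficient from Kd490
#'
#' KdPAR = 0.0864 + 0.884 * Kd490 - 0.00137 / Kd490 (m-1). The reciprocal
#' term diverges as Kd490 approaches zero, so Kd490 must be positive; any
#' chlorophyll-derived Kd490 (>= 0.0166) is safely in range.
#'
#' @param kd490 Attenuation at 490 nm, m-1 (> 0). Vectorized.
#' @return KdPAR in m-1.
#' @export
kdpar_from_kd490 <- function(kd490) {
  if (any(kd490 <= 0, na.rm = TRUE))
    stop("'kd490' must be > 0", call. = FALSE)
  0.0864 + 0.884 * kd490 - 0.00137 / kd490
}

#' Mean PAR over the mixed layer
#'
#' Depth average of Beer-Lambert exponential decay over \[0, mld\]:
#' `par0 * (1 - exp(-kd_par * mld)) / (kd_par * mld)`. This is the analytic
#' integral, not a mid-depth sample, so there is no vertical
#' discretization error.
#'
#' @param par0 PAR just below the surface (> 0), mol photons m-2 d-1.
#' @param kd_par PAR attenuation coefficient, m-1 (> 0).
#' @param mld Mixed-layer depth, m (> 0).
#' @return Mean mixed-layer PAR, same units as `par0`.
#' @export
mixed_layer_mean_par <- function(par0, kd_par, mld) {
  if (any(par0 <= 0) || any(kd_par <= 0) || any(mld <= 0))
    stop("'par0', 'kd_par' and 'mld' must all be > 0", call. = FALSE)
  tau <- kd_par * mld
  par0 * (1 - exp(-tau)) / tau
}

#' Light growth-limiting term
#'
#' Monod form `E / (k_E + E)`, in \[0, 1); 0.5 at the half-saturation
#' irradiance `k_E`.
#'
#' @param e_ml Mean mixed-layer PAR (>= 0).
#' @param k_e Half-saturation irradiance (> 0), same units.
#' @return Dimensionless limitation in \[0, 1).
#' @export
light_limitation <- function(e_ml, k_e) {
  if (any(e_ml < 0)) stop("'e_ml' must be >= 0", call. = FALSE)
  if (any(k_e <= 0)) stop("'k_e' must be > 0", call. = FALSE)
  e_ml / (k_e + e_ml)
}
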