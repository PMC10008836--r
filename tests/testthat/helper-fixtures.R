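# Shared fixtures built in code.

pft_names <- c("diatoms", "coccolithophores", "chlorophytes",
               "dinoflagellates", "cyanobacteria", "phaeocystis")

# A community of six physiologically identical groups (silicate fields only
# on diatoms, with saturating k_si so the silicate term never binds): under
# these parameters growth, sinking and grazing are identical across groups,
# so biomass fractions must stay constant.
uniform_community <- function(mu_max = 1.2, w0 = 0.3) {
  pfts <- lapply(pft_names, function(nm) {
    if (nm == "diatoms")
      pft_params(nm, mu_max = mu_max, k_no3 = 0.5, k_fe = 0.3,
                 k_si = 1e-9, k_e = 4, w0 = w0, r_n_chl = 0.8,
                 r_si_chl = 1e-9, r_fe_chl = 0.02)
    else
      pft_params(nm, mu_max = mu_max, k_no3 = 0.5, k_fe = 0.3,
                 k_e = 4, w0 = w0, r_n_chl = 0.8, r_fe_chl = 0.02)
  })
  community_params(pfts)
}

# Constant forcing over `days`, one sample per day.
constant_forcing <- function(days, sst = 12, par0 = 25, mld = 40,
                             kappa = 0.02, deep_no3 = 8, deep_si = 6,
                             deep_fe = 0.8) {
  f <- make_seasonal_forcing(max(1, ceiling(days / 365)), 1, "subarctic",
                             seed = 1)
  f <- f[seq_len(days), ]
  f$sst <- sst; f$par0 <- par0; f$mld <- mld; f$kappa <- kappa
  f$deep_no3 <- deep_no3; f$deep_si <- deep_si; f$deep_fe <- deep_fe
  class(f) <- c("forcing_series", "data.frame")
  f
}

# A state with all nutrients effectively saturating.
replete_state <- function(chl = setNames(rep(0.5, 6), pft_names)) {
  model_state(as.Date("2001-01-01"), chl,
              no3 = 1e6, nh4 = 0, si = 1e6, fe = 1e6)
}

# Monthly series helper: first-of-month dates for n months from start.
monthly_dates <- function(n, start = as.Date("2001-01-15")) {
  seq(start, by = "month", length.out = n)
}
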