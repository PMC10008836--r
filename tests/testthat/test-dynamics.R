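test_that("temperature factor is the 20 C-normalized exponential", {
  expect_equal(temperature_factor(20), 1)
  expect_equal(temperature_factor(21), 1.066)
  expect_equal(temperature_factor(30), 1.89483783, tolerance = 1e-7)
})

test_that("Monod function hits its landmark values", {
  expect_equal(monod(3, 3), 0.5)
  expect_equal(monod(0, 3), 0)
  expect_equal(monod(27, 3), 0.9)
  expect_error(monod(1, 0), "> 0")
})

test_that("Liebig nutrient limitation picks the scarcest nutrient", {
  p <- default_params()
  diat <- p$pfts$diatoms
  dino <- p$pfts$dinoflagellates

  no_si <- model_state(as.Date("2001-01-01"),
                       setNames(rep(0.5, 6), pft_names),
                       no3 = 1e6, nh4 = 0, si = 0, fe = 1e6)
  lim_d <- nutrient_limitation(no_si, diat)
  expect_equal(lim_d$f_nut, 0)
  expect_equal(lim_d$binding, "Si")
  # dinoflagellates do not require silicate: unaffected by si = 0
  lim_o <- nutrient_limitation(no_si, dino)
  expect_gt(lim_o$f_nut, 1 - 1e-5)

  # exact three-way tie: all Monod terms equal by construction; the
  # value is the common one and the label follows the fixed N, Fe, Si order
  tie <- model_state(as.Date("2001-01-01"),
                     setNames(rep(0.5, 6), pft_names),
                     no3 = diat$k_no3, nh4 = 0, si = diat$k_si,
                     fe = diat$k_fe)
  lim_t <- nutrient_limitation(tie, diat)
  expect_equal(lim_t$f_nut, 0.5)
  expect_equal(lim_t$binding, "N")
})

test_that("growth rate follows the min rule scaled by temperature", {
  p <- pft_params("chlorophytes", mu_max = 1, k_no3 = 0.7, k_fe = 0.3,
                  k_e = 4, w0 = 0.2, r_n_chl = 0.8, r_fe_chl = 0.02)
  st <- replete_state()
  # everything saturating at the reference temperature -> mu_max
  expect_equal(growth_rate(p, st, e_ml = 1e9, t = 20), 1, tolerance = 1e-6)
  # f_nut = 0 shuts growth off regardless of light
  dark_nut <- model_state(st$time, st$chl, no3 = 0, nh4 = 0, si = 0, fe = 0)
  expect_equal(growth_rate(p, dark_nut, e_ml = 1e9, t = 20), 0)
  # f_nut = 0.3 (conc = 3k/7), f_E = 0.8 (e = 4 k_e) -> mu = 0.3
  part <- model_state(st$time, st$chl, no3 = 0.3, nh4 = 0, si = 0,
                      fe = 1e6)
  expect_equal(growth_rate(p, part, e_ml = 16, t = 20), 0.3,
               tolerance = 1e-12)
})

test_that("sinking speed scales linearly with temperature", {
  expect_equal(sinking_rate(1, 0), 0.451)
  expect_equal(sinking_rate(2, 31), 2 * 1.0028, tolerance = 1e-12)
  expect_equal(sinking_rate(0, 15), 0)
  expect_gt(sinking_rate(1, 25), sinking_rate(1, 5))
})

test_that("Ivlev grazing saturates and carries its temperature factor", {
  p <- default_params()
  expect_equal(grazing_rate(0, 10, p), 0)
  rh20 <- 0.06 * exp(2) + 0.7   # 1.14334337
  expect_equal(grazing_rate(1e6, 20, p), p$gamma_m * rh20,
               tolerance = 1e-6)
  expect_equal(grazing_rate(2, 20, p),
               p$gamma_m * rh20 * (1 - exp(-p$ivlev_lambda * 2)),
               tolerance = 1e-12)
})

test_that("tendencies respect the zero-biomass fixed point", {
  p <- default_params()
  f1 <- constant_forcing(2)[1, ]
  dead <- model_state(f1$time, setNames(rep(0, 6), pft_names),
                      no3 = 2, nh4 = 0.5, si = 1, fe = 0.2)
  d <- tendencies(dead, f1, p)
  expect_equal(unname(d$chl), rep(0, 6))
  expect_equal(d$no3, f1$kappa * (f1$deep_no3 - 2))
  expect_equal(d$si, f1$kappa * (f1$deep_si - 1))
  expect_equal(d$fe, f1$kappa * (f1$deep_fe - 0.2))
})

test_that("unlimited growth reduces to the exponential limit", {
  p <- uniform_community(mu_max = 1.2, w0 = 0)
  p$gamma_m <- 0
  f1 <- constant_forcing(2, sst = 20, par0 = 1e9)[1, ]
  st <- replete_state()
  st$chl[] <- 0.001   # negligible self-shading at trace biomass
  d <- tendencies(st, f1, p)
  expect_equal(unname(d$chl / st$chl), rep(1.2, 6), tolerance = 1e-3)
})

test_that("nitrogen budget closes with full recycling and no export", {
  p <- uniform_community(w0 = 0)
  p$recycle_frac <- 1
  f1 <- constant_forcing(2)[1, ]
  f1$kappa <- 0
  st <- model_state(f1$time, setNames(c(0.4, 0.8, 0.2, 0.1, 0.3, 0.6),
                                      pft_names),
                    no3 = 3, nh4 = 0.7, si = 4, fe = 0.5)
  d <- tendencies(st, f1, p)
  r_n <- vapply(p$pfts, `[[`, 0, "r_n_chl")
  dN_total <- d$no3 + d$nh4 + sum(r_n * d$chl)
  expect_equal(dN_total, 0, tolerance = 1e-12)
})

test_that("grazing is composition-neutral for identical physiologies", {
  p <- uniform_community()
  f <- constant_forcing(200)
  init <- model_state(f$time[1],
                      setNames(c(0.9, 0.1, 0.3, 0.5, 0.2, 0.05),
                               pft_names),
                      no3 = 8, nh4 = 0.5, si = 6, fe = 0.8)
  traj <- run_simulation(f, p, init, dt = 1)
  fr <- biomass_fractions(traj)
  drift <- apply(fr, 2, function(x) max(abs(x - x[1])))
  expect_lt(max(drift), 1e-9)
})

test_that("lowering silicate never slows a non-diatom", {
  p <- default_params()
  st_hi <- model_state(as.Date("2001-06-01"),
                       setNames(rep(0.5, 6), pft_names),
                       no3 = 2, nh4 = 0.3, si = 5, fe = 0.4)
  st_lo <- model_state(st_hi$time, st_hi$chl, no3 = 2, nh4 = 0.3,
                       si = 0.01, fe = 0.4)
  for (nm in setdiff(pft_names, "diatoms")) {
    expect_equal(growth_rate(p$pfts[[nm]], st_lo, 10, 12),
                 growth_rate(p$pfts[[nm]], st_hi, 10, 12))
  }
  expect_lt(growth_rate(p$pfts$diatoms, st_lo, 10, 12),
            growth_rate(p$pfts$diatoms, st_hi, 10, 12))
})

test_that("constant forcing settles to a stationary state", {
  p <- default_params()
  f <- constant_forcing(3000)
  traj <- run_simulation(f, p, dt = 1)
  n <- length(traj$time)
  # re-running from the end state stays put (relative to pool sizes)
  init2 <- model_state(f$time[1], traj$chl[n, ], traj$no3[n], traj$nh4[n],
                       traj$si[n], traj$fe[n])
  f2 <- constant_forcing(200)
  traj2 <- run_simulation(f2, p, init2, dt = 1)
  expect_lt(max(abs(traj2$chl_tot - traj2$chl_tot[1])) /
              traj2$chl_tot[1], 1e-3)
  expect_lt(max(abs(traj2$no3 - traj2$no3[1])) / (traj2$no3[1] + 1e-6),
            1e-3)
})

test_that("trajectory bookkeeping: totals, fractions, NaN forcing", {
  f <- make_seasonal_forcing(1, 1, "subarctic", seed = 2)
  traj <- run_simulation(f, dt = 1)
  expect_equal(traj$chl_tot, rowSums(traj$chl))
  fr <- biomass_fractions(traj)
  expect_lt(max(abs(rowSums(fr) - 1)), 1e-12)

  f_bad <- f; f_bad$sst[40] <- NA
  expect_error(run_simulation(f_bad), as.character(f$time[40]))
  f_short <- f; expect_error(run_simulation(f_short, dt = 2),
                             "must not exceed")
})

test_that("degenerate fraction cases behave as documented", {
  f <- constant_forcing(5)
  p <- uniform_community()
  one <- setNames(c(0, 0, 1.3, 0, 0, 0), pft_names)
  traj <- run_simulation(f, p, model_state(f$time[1], one, 5, 0.5, 5, 0.5),
                         dt = 1)
  fr <- biomass_fractions(traj)
  expect_equal(unname(fr[1, ]), c(0, 0, 1, 0, 0, 0))
  dead <- run_simulation(f, p,
                         model_state(f$time[1],
                                     setNames(rep(0, 6), pft_names),
                                     5, 0.5, 5, 0.5), dt = 1)
  expect_true(all(is.na(biomass_fractions(dead))))
})
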