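test_that("monthly climatology averages by calendar month", {
  tt <- monthly_dates(48)
  const <- data.frame(time = tt, value = 3.7)
  clim <- monthly_climatology(const)
  expect_equal(unname(clim$months), rep(3.7, 12))

  # one +X spike in a single January among n Januaries
  spiked <- const
  spiked$value[13] <- 3.7 + 2.4    # second January
  clim2 <- monthly_climatology(spiked)
  expect_equal(clim2$months[["Jan"]] - clim2$months[["Feb"]], 2.4 / 4,
               tolerance = 1e-12)
})

test_that("a missing calendar month in the baseline errors by name", {
  tt <- monthly_dates(36)
  x <- data.frame(time = tt, value = rnorm(36))
  x$value[format(x$time, "%m") == "02"] <- NA
  expect_error(monthly_climatology(x), "February")
  expect_error(monthly_climatology(x[1:20, ]), "two full years")
})

test_that("anomalies are value minus same-month climatology", {
  tt <- monthly_dates(36)
  base <- data.frame(time = tt, value = 2 + cos(2 * pi * (1:36) / 12))
  clim <- monthly_climatology(base)
  a30 <- anomaly(data.frame(time = tt, value = 1.3 * base$value), clim)
  expect_equal(a30$percent, rep(30, 36), tolerance = 1e-9)
  expect_equal(a30$absolute, 0.3 * base$value, tolerance = 1e-12)

  # centering: anomalies of the baseline itself average to zero
  a0 <- anomaly(base, clim)
  expect_lt(abs(mean(a0$absolute)), 1e-10)
})

test_that("deseasonalization annihilates any 12-month periodic signal", {
  tt <- monthly_dates(60)
  for (shape in list(sin(2 * pi * (1:60) / 12),
                     rep(c(5, 1, 4, 2, 8, 3, 9, 2, 7, 1, 6, 2), 5))) {
    s <- data.frame(time = tt, value = 10 + shape)
    a <- anomaly(s, monthly_climatology(s))
    expect_lt(max(abs(a$absolute)), 1e-10)
  }
})

test_that("percent and absolute anomalies are sign-consistent", {
  tt <- monthly_dates(36)
  s <- data.frame(time = tt, value = abs(rnorm(36)) + 0.5)
  a <- anomaly(s, monthly_climatology(s))
  ok <- !is.na(a$percent)
  expect_true(all(sign(a$percent[ok]) == sign(a$absolute[ok])))
})

test_that("rolling mean smooths with shrinking edges", {
  expect_equal(rolling_mean(rep(4, 20), 6), rep(4, 20))
  expect_equal(rolling_mean(1:10, 1), as.numeric(1:10))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- rolling_mean(imp, 6)
  # full centered windows containing the impulse all average to 1/6
  expect_equal(sm[9:14], rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(sm[c(5, 17)], c(0, 0))
  # trailing variant lags the impulse
  tr <- rolling_mean(imp, 6, align = "right")
  expect_equal(tr[11:16], rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("limitation anomalies transform through the diatom Monod term", {
  p <- default_params()
  tt <- monthly_dates(36)
  const <- data.frame(time = tt, value = 2)
  a <- limitation_anomaly(const, "silicate", p$pfts$diatoms)
  expect_equal(a$absolute, rep(0, 36))

  # a drawdown below climatology gives a negative limitation anomaly
  s <- data.frame(time = tt, value = rep(2, 36))
  s$value[30] <- 0.4
  a2 <- limitation_anomaly(s, "nitrate", p$pfts$diatoms)
  expect_lt(a2$absolute[30], 0)
  expect_error(limitation_anomaly(s, "phosphate", p$pfts$diatoms),
               "nitrate, silicate or iron")

  # transform-then-deseasonalize differs from the reverse order because
  # the Monod map is concave: with each calendar month alternating between
  # 0.2 and 4 across years, mean(monod(x)) < monod(mean(x)) (Jensen gap)
  yr <- rep(1:3, each = 12)
  s3 <- data.frame(time = tt, value = ifelse(yr %% 2 == 1, 0.2, 4))
  k <- p$pfts$diatoms$k_no3
  lim_first <- limitation_anomaly(s3, "nitrate", p$pfts$diatoms)
  conc_anom <- anomaly(s3, monthly_climatology(s3))
  reverse <- monod(conc_anom$climatology + conc_anom$absolute, k) -
    monod(conc_anom$climatology, k)
  expect_gt(max(abs(lim_first$absolute - reverse)), 0.05)
})

test_that("dominance classification joins anomalies with the argmax group", {
  f <- make_seasonal_forcing(3, 1, "subarctic", seed = 5)
  traj <- run_simulation(f, dt = 1)
  chl_m <- monthly_means(traj$time, traj$chl_tot)
  sst_m <- monthly_means(f$time, f$sst)
  chl_a <- anomaly(chl_m, monthly_climatology(chl_m))
  sst_a <- anomaly(sst_m, monthly_climatology(sst_m))
  rec <- dominance(traj, sst_a, chl_a)
  expect_equal(nrow(rec), nrow(chl_a))
  # recompute one month by hand
  fr <- biomass_fractions(traj)
  m1 <- format(traj$time, "%Y-%m") == "2002-06"
  expect_equal(rec$dominant[rec$time == as.Date("2002-06-01")],
               pft_names[which.max(colMeans(fr[m1, ]))])
  expect_error(dominance(traj, sst_a[-1, ], chl_a), "misaligned")
})

test_that("dominance ties break to the lexicographically first name", {
  tt <- as.Date("2001-01-01") + 0:59
  chl <- matrix(0, 60, 6, dimnames = list(NULL, pft_names))
  chl[, "diatoms"] <- 0.5
  chl[, "chlorophytes"] <- 0.5
  traj <- structure(list(time = tt, chl = chl, chl_tot = rowSums(chl)),
                    class = "pft_trajectory")
  an <- structure(data.frame(time = as.Date(c("2001-01-01", "2001-02-01")),
                             absolute = c(0, 0)),
                  class = c("anomaly_series", "data.frame"))
  rec <- dominance(traj, an, an)
  expect_equal(unique(rec$dominant), "chlorophytes")
})
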