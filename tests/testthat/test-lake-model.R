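test_that("nitrate supply follows the catchment-scaled lightning budget", {
  expect_equal(nitrate_supply_rate(lake_config(depth = 1)), 6.5e-14,
               tolerance = 1e-12)
  expect_equal(nitrate_supply_rate(lake_config(catchment = 0)), 0)
  # sigma/V halves per metre of depth: the 5 m lake gets one fifth
  expect_equal(nitrate_supply_rate(lake_config(depth = 5)),
               nitrate_supply_rate(lake_config(depth = 1)) / 5)
})

test_that("haze-phase initial state carries the accumulated budgets", {
  cfg <- lake_config(depth = 1)
  st <- init_haze_phase(cfg)
  expect_equal(nrow(st), 100)
  expect_true(all(st$A == 0.1)) # stated favourable starting concentration
  expect_true(all(st$B == 0))
  # nitrate accumulated over 1e3 yr at the supply rate
  expect_equal(st$N, rep(6.5e-14 * 1e3 * 3.156e7, 100), tolerance = 1e-9)
  # rainout-derived mode: C * Phi * t / (6 N_A d), six cyanides per complex
  cfg2 <- lake_config(depth = 1, initial_ferrocyanide = NULL)
  expected <- 500 * (1e8 * 1e4) * (1e3 * 3.156e7) / 1 / 6.022e23 / 1e3 / 6
  expect_equal(init_haze_phase(cfg2)$A[1], min(0.1, expected))
  expect_lt(expected, 0.1) # the rainout budget does not reach the cap
  # no haze phase, nothing accumulated
  st0 <- init_haze_phase(lake_config(haze_duration = 0))
  expect_true(all(st0$A == 0) && all(st0$N == 0) && all(st0$B == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(lake_config(depth = 0.015, layer_thickness = 0.01), "multiple")
  expect_error(lake_config(k2 = -1), ">= 0")
  expect_error(lake_config(k2 = 2e-4), "Unstable")
  expect_error(lake_config(survival_threshold = 2), "survival_threshold")
})

test_that("layer transmission is the decadal Beer-Lambert factor per transit", {
  cfg <- lake_config(depth = 0.02)
  curves <- default_lake_curves(grid = lake_grid(cfg))
  st <- init_haze_phase(cfg)
  # empty column transmits everything
  st0 <- st; st0$A <- 0; st0$N <- 0
  z0 <- layer_transmission(st0, curves, cfg)
  expect_true(all(z0$z == 1))
  # 0.1 M over 1 cm at the 340 nm peak: decadal optical depth 22
  z <- layer_transmission(st, curves, cfg)
  expect_equal(z$z[z$layer == 1 & z$wavelength == 340], 10^-22, tolerance = 1e-9)
  # 0.1 mM over 1 cm: decadal optical depth 0.022
  st2 <- st; st2$A <- 1e-4
  z2 <- layer_transmission(st2, curves, cfg)
  expect_equal(z2$z[z2$layer == 1 & z2$wavelength == 340], 10^-0.022,
               tolerance = 1e-9)
  # missing band coverage is rejected
  expect_error(
    layer_transmission(st, dplyr::filter(curves, wavelength >= 250), cfg),
    "cover"
  )
})

test_that("band flux ratios multiply through stacked layers", {
  grid <- 300:309
  flux <- tibble::tibble(wavelength = grid, flux = 1)
  uniform <- function(z, layers) {
    tibble::tibble(
      layer = rep(seq_len(layers), each = length(grid)),
      wavelength = rep(grid, layers),
      z = z
    )
  }
  # transparent column
  expect_true(all(chi_profile(flux, uniform(1, 3), c(300, 310))$chi == 1))
  # one uniform decadal optical depth
  one <- chi_profile(flux, uniform(0.1, 1), c(300, 310))
  expect_equal(one$chi, c(1, 0.1))
  # two identical layers: chi_2 = chi_1^2
  two <- chi_profile(flux, uniform(0.1, 2), c(300, 310))
  expect_equal(two$chi[3], two$chi[2]^2)
  expect_error(
    chi_profile(tibble::tibble(wavelength = grid, flux = 0), uniform(1, 1),
                c(300, 310)),
    "band"
  )
})

test_that("a fully shaded layer only accumulates nitrate", {
  cfg <- lake_config(depth = 0.01)
  st <- init_haze_phase(cfg)
  adv <- lake_step(st, chi_k1 = 0, chi_k2 = 0, cfg)
  expect_equal(adv$A, st$A)
  expect_equal(adv$B, st$B)
  expect_equal(adv$N, st$N + nitrate_supply_rate(cfg) * 86400 * cfg$dt)
})

test_that("an unshaded single layer matches the closed-form kinetics", {
  cfg <- lake_config(depth = 0.01, horizon = 10)
  sim <- run_lake(cfg)
  # ferrocyanide: pure exponential at k1 + k2; 1% survival
  expect_equal(sim$survival$time, log(100) / (K1_DAY + K2_DAY),
               tolerance = 5e-3)
  # nitroprusside transient peak: A0 (e^-k2 t* - e^-(k1+k2) t*)
  tstar <- log(1 + K1_DAY / K2_DAY) / K1_DAY
  peak <- 0.1 * (exp(-K2_DAY * tstar) - exp(-(K1_DAY + K2_DAY) * tstar))
  expect_equal(sim$peak_B$peak_B, peak, tolerance = 5e-3)
  # full trajectory against the analytic solution at the recorded times
  traj <- tidy(sim)
  traj <- traj[traj$time > 0 & traj$A > 0, ]
  expect_equal(traj$A, 0.1 * exp(-(K1_DAY + K2_DAY) * traj$time),
               tolerance = 5e-3)
})

test_that("switching off photo-oxidation leaves nitroprusside at zero", {
  cfg <- lake_config(depth = 0.01, k1 = 0, horizon = 10)
  sim <- run_lake(cfg)
  expect_true(all(sim$peak_B$peak_B == 0))
  expect_equal(sim$survival$time, log(100) / K2_DAY, tolerance = 5e-3)
})

test_that("chi ordering and concentration positivity hold along a run", {
  cfg <- quick_lake(depth = 0.05)
  sim <- run_lake(cfg)
  traj <- tidy(sim)
  expect_true(all(traj$A >= 0 & traj$B >= 0 & traj$N >= 0))
  expect_true(all(traj$A <= 0.1 + 1e-15)) # never exceeds the post-haze start
  recorded <- traj[traj$time > 0, ]
  by_time <- split(recorded, recorded$time)
  for (snap in by_time) {
    snap <- snap[order(snap$layer), ]
    expect_true(all(diff(snap$chi_k1) <= 1e-12))
    expect_true(all(diff(snap$chi_k2) <= 1e-12))
  }
})

test_that("an opaque layer freezes the layer below it (sequential burn-down)", {
  # flat curves give every bin of both bands a decadal optical depth of 20
  cfg <- lake_config(depth = 0.02, horizon = 1, record_every = 1)
  curves <- flat_curves(lake_grid(cfg), eps_ferro = 2000)
  sim <- run_lake(cfg, curves = curves)
  traj <- tidy(sim)
  deep <- traj[traj$layer == 2, ]
  deep <- deep[order(deep$time), ]
  top <- traj[traj$layer == 1, ]
  top <- top[order(top$time), ]
  # while the surface layer retains a decadal optical depth of at least 10
  shaded <- top$A[-nrow(top)] * 2000 * 0.1 >= 10
  rel_change <- abs(diff(deep$A)) / deep$A[-nrow(deep)]
  expect_true(any(shaded))
  expect_true(all(rel_change[shaded] < 1e-8))
  # while the surface layer decays at full speed
  top <- traj[traj$layer == 1, ]
  expect_lt(min(top$A), 0.1 * exp(-K2_DAY * 0.9))
})

test_that("halving the time step moves survival times by less than 2%", {
  base <- run_lake(lake_config(depth = 0.05, horizon = 50, dt = 0.07))
  half <- run_lake(lake_config(depth = 0.05, horizon = 50, dt = 0.035))
  expect_false(any(base$survival$censored) || any(half$survival$censored))
  rel <- abs(base$survival$time - half$survival$time) / half$survival$time
  expect_lt(max(rel), 0.02)
})

test_that("survival bookkeeping: monotone in depth, censoring, thresholds", {
  cfg <- quick_lake(depth = 0.05)
  sim <- run_lake(cfg)
  sv <- survival_times(sim)
  expect_true(all(diff(sv$time) >= -1e-9)) # deeper never dies sooner
  # at a 100% threshold survival is immediate
  expect_true(all(survival_times(sim, 1)$time == 0))
  # a laxer threshold is crossed no later
  sv2 <- survival_times(sim, 0.05)
  expect_false(any(sv2$censored))
  expect_true(all(sv2$time <= sv$time + 1e-9))
  # horizon too short: censored layers
  short <- run_lake(lake_config(depth = 0.05, horizon = 1))
  expect_true(any(short$survival$censored))
  # horizon zero: only the initial state
  none <- run_lake(lake_config(depth = 0.05, horizon = 0))
  expect_equal(unique(none$trajectory$time), 0)
})

test_that("shadow slope fitting and extrapolation", {
  # an exactly linear profile is recovered exactly
  sv <- tibble::tibble(
    layer = 1:5, depth = (1:5) / 100,
    time = 3 * (1:5) / 100, censored = FALSE
  )
  fit <- suppressWarnings(shadow_slope(sv))
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(predict(fit, 10), 30)
  # censored points are excluded; too few points rejected
  sv$censored[3:5] <- TRUE
  expect_error(shadow_slope(sv), "3 uncensored")
  expect_equal(glance(fit)$slope, 3)
})

test_that("thin-column shadow slope grows with band width", {
  slope_for <- function(width) {
    cfg <- lake_config(depth = 0.5, initial_ferrocyanide = 1e-4,
                       horizon = 30, record_every = 50)
    sim <- run_lake(cfg, curves = default_lake_curves(lake_grid(cfg), width))
    shadow_slope(sim)$slope
  }
  # wider bands absorb more of the 300-400 nm band, deepening the shadow
  expect_gt(slope_for(60), slope_for(25))
})

test_that("the shadow slope is robust to the in-band flux shape at 0.1 M", {
  cfg <- lake_config(depth = 0.3, horizon = 100, record_every = 50)
  flat <- run_lake(cfg, flux = make_actinic_flux(lake_grid(cfg), "flat"))
  bb <- run_lake(cfg, flux = make_actinic_flux(lake_grid(cfg), "blackbody"))
  s_flat <- shadow_slope(flat)$slope
  s_bb <- shadow_slope(bb)$slope
  expect_lt(abs(s_flat - s_bb) / s_flat, 0.10)
})

test_that("exposure delay and protected lifetimes add up", {
  cfg <- quick_lake(depth = 0.05)
  sim <- run_lake(cfg)
  delay <- exposure_delay(sim)
  expect_equal(delay, max(sim$survival$time))
  expect_equal(protected_lifetime(0, 42), 42)
  expect_equal(protected_lifetime(delay, 10), delay + 10)
  expect_error(protected_lifetime(-1, 10), ">= 0")
})
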