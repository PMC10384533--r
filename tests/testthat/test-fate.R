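# two-film parameters with a unit gas-side group: Ng = P/(Rg (Tem+273.15)),
# a1 = a2 = 0, so the gas-film resistance reduces to 1/k_g exactly
two_film <- function(k_l, k_g, Tem = 15, ...) {
  P <- 101325; Rg <- 8.314
  fate_params(k_l = k_l, k_g = k_g, a1 = 0, a2 = 0, Tem = Tem, P = P,
              Rg = Rg, Ng = P / (Rg * (Tem + 273.15)), ...)
}

test_that("hot start lays down the inside/outside concentrations", {
  g <- small_bay()
  s0 <- hot_start_init(g, initial_condition(0, 0, 0))
  expect_true(all(s0$C == 0) && all(s0$C_sed == 0) && all(s0$dep_cum == 0))
  s <- hot_start_init(g, initial_condition(50, 10, 5))
  expect_true(all(s$C[sea_cells(g)] == 50))
  expect_true(all(s$C[open_cells(g)] == 10))
  # volume-weighted mass oracle
  hyd <- hydro_state(g)
  m <- water_mass(s, hyd, g)
  vol_in <- sum(g$H[sea_cells(g)]) * g$area * 1000
  vol_bd <- sum(g$H[open_cells(g)]) * g$area * 1000
  expect_rel_equal(m, 50 * vol_in + 10 * vol_bd, 1e-12)
  expect_error(hot_start_init(g, initial_condition(-1, 0, 0)), "non-negative")
})

test_that("two-film volatilization coefficient behaves as series resistances", {
  # liquid-film-limited limit: enormous gas film coefficient
  p <- two_film(k_l = 3, k_g = 1e12)
  expect_rel_equal(volatilization_coefficient(p), 3, 1e-9)
  # equal resistances halve the liquid-film coefficient
  p <- two_film(k_l = 4.15, k_g = 4.15)
  expect_equal(volatilization_coefficient(p), 2.075, tolerance = 1e-12)
  # strictly increasing in k_l, never above k_l
  ks <- seq(0.5, 8, by = 0.5)
  kv <- vapply(ks, function(k) volatilization_coefficient(two_film(k, 0.9)), 0)
  expect_true(all(diff(kv) > 0))
  expect_true(all(kv < ks & kv > 0))
})

test_that("air-sea exchange rate is the depth-normalized departure from equilibrium", {
  p <- two_film(k_l = 1, k_g = 1e12, C_equ = 0)
  expect_rel_equal(air_sea_sink(10, p, 10), 1.0, 1e-9)
  pe <- two_film(k_l = 2, k_g = 1, C_equ = 7)
  expect_equal(air_sea_sink(7, pe, 5), 0)
  expect_lt(air_sea_sink(3, pe, 5), 0)  # invasion when undersaturated
  expect_error(air_sea_sink(1, pe, 0), "positive")
})

test_that("seepage velocity and bed exchange follow the upwinded gradient law", {
  p <- fate_params(phi = 0.5, D_sw = 0.014, L_sw = 0.1)
  csed_star <- function(C_sed) C_sed * p$rho_b * 1000
  # (C_sed* - C_s) = 100 with the Table-4 diffusion coefficient
  C_sed <- 100 / (p$rho_b * 1000)
  expect_equal(seepage_velocity(C_sed, 0, p), 7.0, tolerance = 1e-12)
  expect_equal(seepage_velocity(C_sed, csed_star(C_sed), p), 0)
  p0 <- fate_params(phi = 0, D_sw = 0.014, L_sw = 0.1)
  expect_equal(seepage_velocity(10, 0, p0), 0)
  # upwinding by sign, continuous at vp = 0
  part <- phase_partition()
  C_sed200 <- 200 / (p$rho_b * 1000)
  vp <- seepage_velocity(C_sed200, 0, p)
  expect_equal(bed_exchange_flux(0, C_sed200, p, part), vp * 200)
  expect_equal(bed_exchange_flux(csed_star(C_sed200), C_sed200, p, part), 0)
  # deposition-side branch carries the mobile (particulate + dissolved) share
  vneg <- seepage_velocity(0, 50, p)
  expect_lt(vneg, 0)
  expect_equal(bed_exchange_flux(50, 0, p, part),
               vneg * 50 * (part$particulate + part$dissolved))
})

test_that("degradation is affine with the printed reaction constants", {
  p <- fate_params(K0 = 0.003, K1 = 0.017, Kt = 1)
  expect_equal(degradation_sink(0, fate_params(K0 = 0)), 0)
  expect_equal(degradation_sink(100, p), 1.703, tolerance = 1e-12)
  expect_equal(degradation_sink(51, p) - degradation_sink(50, p),
               0.017, tolerance = 1e-12)
})

test_that("settling velocity is omega-scaled physical Stokes law", {
  expect_equal(settling_velocity(fate_params(rhoT = 1024.2)), 0)
  expect_equal(settling_velocity(fate_params(omega = 0)), 0)
  p <- fate_params(omega = 1, d_p = 50e-6, rhoT = 2000, rho0 = 1024.2,
                   Ve = 1.5e-6, g = 9.81)
  oracle <- 1 * 9.81 * (50e-6)^2 * (2000 - 1024.2) / (18 * 1.5e-6 * 1024.2) * 86400
  expect_rel_equal(settling_velocity(p), oracle, 1e-12)
  expect_equal(oracle, 74.77, tolerance = 1e-3)  # regression lock, m/d
  # buoyant particles get a negative velocity
  expect_lt(settling_velocity(fate_params(rhoT = 900)), 0)
})

test_that("transport leaves a still, source-free field unchanged", {
  g <- small_bay()
  hyd <- hydro_state(g)
  hyd$t <- 300
  pah <- hot_start_init(g, initial_condition(50, 50, 0))
  out <- step_transport(pah, hyd, g, tracer_params(), phase_partition(),
                        NULL, 300, c_outside = 50)
  expect_equal(out$C, pah$C, tolerance = 1e-14)
})

test_that("closed-basin tracer mass is conserved under sloshing flow", {
  g <- close_mouth(small_bay())
  hp <- hydro_params(dt = 30, eddy_visc = 0)
  fp <- tracer_params(sigma_tx = 5, sigma_ty = 5)
  hyd <- hydro_state(g); hyd$zeta[10, 5] <- 0.5
  pah <- hot_start_init(g, initial_condition(50, 0, 0))
  set.seed(2)
  pah$C[sea_cells(g)] <- runif(sum(sea_cells(g)), 10, 90)
  f0 <- make_default_forcing()
  m0 <- water_mass(pah, hyd, g, hp$min_depth)
  for (i in 1:1000) {
    hyd <- step_hydro(hyd, g, hp, f0)
    pah <- step_transport(pah, hyd, g, fp, phase_partition(), NULL, hp$dt,
                          0, hp$min_depth)
  }
  m1 <- water_mass(pah, hyd, g, hp$min_depth)
  expect_lt(abs(m1 - m0) / m0, 1e-8)
  expect_true(all(pah$C >= 0))
})

test_that("a Gaussian patch advects and spreads per the closed-form solution", {
  nx <- 300; dx <- 100; D0 <- 10; u <- 0.5; dt <- dx / u
  g <- channel_grid(nx, dx = dx, H0 = D0, dy = 100)
  sig <- 1.0
  fp <- tracer_params(sigma_tx = sig, sigma_ty = sig)
  hyd <- hydro_state(g)
  hyd$qx[2:nx, 1] <- dt * D0 * u
  pah <- hot_start_init(g, initial_condition(0, 0, 0))
  x <- (seq_len(nx) - 0.5) * dx
  x0 <- 5000; sd0 <- 500
  pah$C[, 1] <- exp(-(x - x0)^2 / (2 * sd0^2))
  nsteps <- 40
  for (n in seq_len(nsteps)) {
    hyd$t <- hyd$t + dt
    pah <- step_transport(pah, hyd, g, fp, phase_partition(), NULL, dt, 0)
  }
  tt <- nsteps * dt
  Cn <- pah$C[, 1]
  m <- sum(Cn); mu <- sum(x * Cn) / m; v <- sum((x - mu)^2 * Cn) / m
  expect_rel_equal(mu, x0 + u * tt, 1e-12)
  expect_rel_equal(v, sd0^2 + 2 * sig * tt, 0.02)
  sd_t <- sqrt(sd0^2 + 2 * sig * tt)
  Cexact <- sd0 / sd_t * exp(-(x - (x0 + u * tt))^2 / (2 * sd_t^2))
  expect_lt(max(abs(Cn - Cexact)) / max(Cexact), 0.02)
})

test_that("tracer transport commutes with grid mirroring", {
  g <- close_mouth(small_bay(12, 6))
  hp <- hydro_params(dt = 60, f = 0, eddy_visc = 0)
  fp <- tracer_params(sigma_tx = 2, sigma_ty = 2)
  hyd <- hydro_state(g); hyd$zeta[4, 3] <- 0.3; hyd$zeta[4, 4] <- 0.3
  pah <- hot_start_init(g, initial_condition(0, 0, 0))
  pah$C[8, 3] <- 100; pah$C[8, 4] <- 100  # symmetric patch
  f0 <- make_default_forcing()
  for (i in 1:100) {
    hyd <- step_hydro(hyd, g, hp, f0)
    pah <- step_transport(pah, hyd, g, fp, phase_partition(), NULL, hp$dt,
                          0, hp$min_depth)
  }
  expect_equal(pah$C, pah$C[, g$ny:1], tolerance = 1e-12)
})

test_that("every step preserves non-negativity across random admissible parameters", {
  g <- small_bay(10, 5)
  hp <- hydro_params(dt = 120)
  f <- make_default_forcing(c(M2 = 0.8))
  set.seed(31)
  for (rep in 1:8) {
    fp <- fate_params(Ve = runif(1, 1.44, 1.57) * 1e-6,
                      D_sw = runif(1, 0.012, 0.015),
                      k_g = runif(1, 0.73, 0.78),
                      k_l = runif(1, 4.12, 4.19),
                      K0 = runif(1, 0, 0.01), K1 = runif(1, 0, 0.05),
                      omega = runif(1), phi = runif(1),
                      d_p = runif(1, 1e-6, 5e-5),
                      C_equ = runif(1, 0, 20))
    hyd <- hydro_state(g)
    pah <- hot_start_init(g, initial_condition(runif(1, 0, 100),
                                               runif(1, 0, 20),
                                               runif(1, 0, 10)))
    for (i in 1:25) {
      hyd <- step_hydro(hyd, g, hp, f)
      pah <- step_transport(pah, hyd, g, fp, phase_partition(), NULL, hp$dt,
                            0, hp$min_depth)
    }
    expect_true(all(pah$C >= 0))
    expect_true(all(pah$C_sed >= 0))
  }
})

test_that("the closed-basin mass ledger closes exactly", {
  g <- close_mouth(small_bay())
  hp <- hydro_params(dt = 60, eddy_visc = 1)
  fp <- fate_params()
  hyd <- hydro_state(g); hyd$zeta[10, 5] <- 0.3
  pah <- hot_start_init(g, initial_condition(50, 0, 5))
  f0 <- make_default_forcing()
  m0 <- water_mass(pah, hyd, g, hp$min_depth)
  cum <- c(adv_net = 0, source_in = 0, volatilized = 0, degraded = 0, bed_net = 0)
  for (i in 1:500) {
    hyd <- step_hydro(hyd, g, hp, f0)
    pah <- step_transport(pah, hyd, g, fp, phase_partition(), NULL, hp$dt,
                          0, hp$min_depth)
    cum <- cum + attr(pah, "ledger")
  }
  m1 <- water_mass(pah, hyd, g, hp$min_depth)
  lost <- m0 - m1
  accounted <- cum[["degraded"]] + cum[["volatilized"]] + cum[["bed_net"]]
  expect_rel_equal(lost, accounted, 1e-6)
})

test_that("annual bed flux integrates the deposition field", {
  g <- small_bay(10, 10)  # 500 m cells
  dep <- matrix(10, 10, 10)
  res <- annual_bed_flux(dep, g)
  area_sea <- sum(sea_cells(g)) * g$area
  expect_equal(res$total_ng_per_yr, 10 * area_sea * 365)
  expect_equal(annual_bed_flux(dep * 0, g)$total_ng_per_yr, 0)
  expect_equal(annual_bed_flux(dep * 2, g)$total_ng_per_yr,
               2 * res$total_ng_per_yr)
  expect_equal(res$mean, 10)
})

test_that("raising omega or particle size never lowers the annual bed flux", {
  g <- small_bay(15, 6)
  hp <- hydro_params(dt = 300)
  f <- make_default_forcing(c(M2 = 0.9))
  src <- source_set(13, 3, 1e7, g)
  flux_for <- function(omega = 0.45, d_p = 5e-6) {
    fp <- fate_params(omega = omega, d_p = d_p)
    run <- run_coupled(g, hp, f, fp, phase_partition(),
                       initial_condition(50, 10, 5), src,
                       duration_s = 2 * 86400, stride = 12L)
    annual_bed_flux(run$dep_mean, g)$total_ng_per_yr
  }
  f_om <- c(flux_for(omega = 0.2), flux_for(omega = 0.45), flux_for(omega = 0.8))
  expect_true(all(diff(f_om) >= 0))
  f_dp <- c(flux_for(d_p = 2e-6), flux_for(d_p = 5e-6), flux_for(d_p = 1e-5))
  expect_true(all(diff(f_dp) >= 0))
})
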