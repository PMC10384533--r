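# Depth-averaged shallow-water solver on the bay grid.
#
# Arakawa C staggering: free surface zeta at cell centres (nx x ny), U at
# x-faces ((nx+1) x ny, face i sits between cells i-1 and i), V at y-faces
# (nx x (ny+1)).  Time stepping is alternating-direction implicit in the
# Leendertse style: an x-sweep solving zeta and U implicitly (tridiagonal
# systems row by row), then a y-sweep for zeta and V.  Continuity is applied
# in flux form, so basin volume is conserved to rounding in closed domains.

#' Hydrodynamic parameters
#'
#' @param g gravitational acceleration (m/s^2).
#' @param rho0 seawater density (kg/m^3).
#' @param f Coriolis parameter (1/s); default computed for latitude 39.4 N.
#' @param chezy Chezy bottom-friction coefficient (m^(1/2)/s).
#' @param CD wind-stress drag coefficient (dimensionless).
#' @param rhoA air density (kg/m^3).
#' @param wind_speed wind speed at 10 m (m/s).
#' @param wind_dir direction the wind blows toward, radians anticlockwise
#'   from the +x (along-channel) axis.
#' @param eddy_visc horizontal eddy viscosity (m^2/s).
#' @param dt time step (s).
#' @param min_depth flooding floor for the total depth (m).
#' @return `hydro_params` list.
#' @export
hydro_params <- function(g = 9.81, rho0 = 1024.2,
                         f = 2 * 7.292115e-5 * sin(39.4 * pi / 180),
                         chezy = 45, CD = 0.0013, rhoA = 1.225,
                         wind_speed = 0, wind_dir = 0,
                         eddy_visc = 10.1, dt = 300, min_depth = 0.1) {
  p <- list(g = g, rho0 = rho0, f = f, chezy = chezy, CD = CD, rhoA = rhoA,
            wind_speed = wind_speed, wind_dir = wind_dir,
            eddy_visc = eddy_visc, dt = dt, min_depth = min_depth)
  if (!(g > 0 && rho0 > 0 && chezy > 0 && dt > 0)) {
    .stopf("g, rho0, chezy and dt must be positive")
  }
  if (CD < 0 || rhoA < 0 || eddy_visc < 0 || wind_speed < 0 || min_depth < 0) {
    .stopf("CD, rhoA, eddy_visc, wind_speed and min_depth must be non-negative")
  }
  class(p) <- "hydro_params"
  p
}

#' Initial (at-rest) hydrodynamic state
#'
#' @param grid a [bay_grid()].
#' @return `hydro_state` with fields `zeta` (nx x ny, m), `U` ((nx+1) x ny,
#'   m/s), `V` (nx x (ny+1), m/s), `qx`/`qy` (per-step face volume fluxes per
#'   unit width, m^2) and `t` (s).
#' @export
hydro_state <- function(grid) {
  structure(
    list(zeta = matrix(0, grid$nx, grid$ny),
         U = matrix(0, grid$nx + 1, grid$ny),
         V = matrix(0, grid$nx, grid$ny + 1),
         qx = matrix(0, grid$nx + 1, grid$ny),
         qy = matrix(0, grid$nx, grid$ny + 1),
         t = 0),
    class = "hydro_state"
  )
}

#' Wind-stress magnitude
#'
#' Quadratic drag law `tau = CD * rhoA * W^2`.  Decomposition into components
#' by wind direction is the caller's job.
#'
#' @param CD drag coefficient; @param rhoA air density (kg/m^3);
#' @param W wind speed at 10 m (m/s).  All must be non-negative.
#' @return Stress magnitude (N/m^2).
#' @export
wind_stress <- function(CD, rhoA, W) {
  if (CD < 0 || rhoA < 0 || W < 0) .stopf("wind_stress arguments must be non-negative")
  CD * rhoA * W^2
}

#' Explicit-stability guide time step
#'
#' Returns `safety * min(dx, dy) / sqrt(g * H_max)`, the barotropic-wave
#' Courant limit of an explicit scheme on this grid.  The ADI scheme is
#' implicit in the wave terms and remains stable above it, but accuracy
#' degrades; [run_hydro()] warns when `dt` exceeds this guide value.
#'
#' @param grid a [bay_grid()]; @param params [hydro_params()];
#' @param safety multiplicative safety factor.
#' @return Maximum advisable time step (s).
#' @export
cfl_limit <- function(grid, params, safety = 1) {
  hmax <- max(grid$H[wet_cells(grid)])
  safety * min(grid$dx, grid$dy) / sqrt(params$g * hmax)
}

# Static geometry shared by every step: wet/open masks and active-face masks.
.hydro_workspace <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  wet <- grid$mask != MASK_LAND
  uact <- matrix(FALSE, nx + 1, ny)
  uact[2:nx, ] <- wet[1:(nx - 1), , drop = FALSE] & wet[2:nx, , drop = FALSE]
  vact <- matrix(FALSE, nx, ny + 1)
  if (ny >= 2) {
    vact[, 2:ny] <- wet[, 1:(ny - 1), drop = FALSE] & wet[, 2:ny, drop = FALSE]
  }
  list(nx = nx, ny = ny, dx = grid$dx, dy = grid$dy, area = grid$area,
       H = grid$H, wet = wet, open = grid$mask == MASK_OPEN,
       interior = grid$mask == MASK_SEA, uact = uact, vact = vact)
}

# upwind gradient of M along rows given the advecting velocity (same shape)
.upwind_dx <- function(M, vel, dx) {
  ifelse(vel > 0, (M - .shift_up(M)) / dx, (.shift_dn(M) - M) / dx)
}
.upwind_dy <- function(M, vel, dy) {
  ifelse(vel > 0, (M - .shift_lf(M)) / dy, (.shift_rt(M) - M) / dy)
}
.laplacian <- function(M, dx, dy) {
  (.shift_up(M) - 2 * M + .shift_dn(M)) / dx^2 +
    (.shift_lf(M) - 2 * M + .shift_rt(M)) / dy^2
}

# One ADI step.  ws is a .hydro_workspace.
.step_hydro_core <- function(st, ws, p, forcing, ramp_s = 0) {
  g <- p$g; dt <- p$dt; dx <- ws$dx; dy <- ws$dy
  nx <- ws$nx; ny <- ws$ny
  zeta <- st$zeta; U <- st$U; V <- st$V
  t0 <- st$t
  ramp <- function(t) if (ramp_s > 0) min(1, t / ramp_s) else 1
  zb_half <- boundary_elevation(forcing, t0 + dt / 2) * ramp(t0 + dt / 2)
  zb_full <- boundary_elevation(forcing, t0 + dt) * ramp(t0 + dt)
  tau <- wind_stress(p$CD, p$rhoA, p$wind_speed)
  taux <- tau * cos(p$wind_dir)
  tauy <- tau * sin(p$wind_dir)

  face_depths <- function(z) {
    D <- pmax(ws$H + z, p$min_depth)
    D[!ws$wet] <- 0
    Du <- matrix(0, nx + 1, ny)
    Du[2:nx, ] <- 0.5 * (D[1:(nx - 1), , drop = FALSE] + D[2:nx, , drop = FALSE])
    Du[!ws$uact] <- 0
    Dv <- matrix(0, nx, ny + 1)
    if (ny >= 2) {
      Dv[, 2:ny] <- 0.5 * (D[, 1:(ny - 1), drop = FALSE] + D[, 2:ny, drop = FALSE])
    }
    Dv[!ws$vact] <- 0
    list(D = D, Du = Du, Dv = Dv)
  }

  ## ---- stage 1: x-implicit (zeta, U), V frozen --------------------------
  fd <- face_depths(zeta)
  Du <- fd$Du; Dv <- fd$Dv
  Vbar <- matrix(0, nx + 1, ny)
  Vbar[2:nx, ] <- 0.25 * (V[1:(nx - 1), 1:ny, drop = FALSE] +
                          V[1:(nx - 1), 2:(ny + 1), drop = FALSE] +
                          V[2:nx, 1:ny, drop = FALSE] +
                          V[2:nx, 2:(ny + 1), drop = FALSE])
  Du_s <- pmax(Du, p$min_depth)
  EU <- p$f * Vbar -
    U * .upwind_dx(U, U, dx) -
    Vbar * .upwind_dy(U, Vbar, dy) +
    taux / (p$rho0 * Du_s) +
    p$eddy_visc * .laplacian(U, dx, dy)
  cf <- g * sqrt(U^2 + Vbar^2) / (Du_s * p$chezy^2)
  Dfr <- 1 + dt * cf
  Ut <- (U + dt * EU) / Dfr
  Ut[!ws$uact] <- 0
  gam <- (g * dt / dx) / Dfr
  gam[!ws$uact] <- 0
  lam <- Du * gam * dt / (2 * dx)          # (nx+1) x ny

  ydiv <- (Dv[, 2:(ny + 1), drop = FALSE] * V[, 2:(ny + 1), drop = FALSE] -
           Dv[, 1:ny, drop = FALSE] * V[, 1:ny, drop = FALSE]) / dy
  rhs <- zeta -
    (dt / (2 * dx)) * (Du[2:(nx + 1), , drop = FALSE] * Ut[2:(nx + 1), , drop = FALSE] -
                       Du[1:nx, , drop = FALSE] * Ut[1:nx, , drop = FALSE]) -
    (dt / 2) * ydiv
  a <- -lam[1:nx, , drop = FALSE]
  b <- 1 + lam[1:nx, , drop = FALSE] + lam[2:(nx + 1), , drop = FALSE]
  cc <- -lam[2:(nx + 1), , drop = FALSE]
  fix <- ws$open | !ws$wet                  # clamped rows
  a[fix] <- 0; cc[fix] <- 0; b[fix] <- 1
  rhs[ws$open] <- zb_half
  rhs[!ws$wet] <- 0
  zhalf <- .tridiag_batch(a, b, cc, rhs)

  dzU <- matrix(0, nx + 1, ny)
  dzU[2:nx, ] <- zhalf[2:nx, , drop = FALSE] - zhalf[1:(nx - 1), , drop = FALSE]
  U <- Ut - gam * dzU
  U[!ws$uact] <- 0
  qx1 <- (dt / 2) * Du * U
  qy1 <- (dt / 2) * Dv * V
  zs1 <- zeta -
    (qx1[2:(nx + 1), , drop = FALSE] - qx1[1:nx, , drop = FALSE]) / dx -
    (qy1[, 2:(ny + 1), drop = FALSE] - qy1[, 1:ny, drop = FALSE]) / dy
  zs1[ws$open] <- zb_half
  zs1[!ws$wet] <- 0

  ## ---- stage 2: y-implicit (zeta, V), U frozen --------------------------
  fd2 <- face_depths(zs1)
  Du2 <- fd2$Du; Dv2 <- fd2$Dv
  Ubar <- matrix(0, nx, ny + 1)
  if (ny >= 2) {
    Ubar[, 2:ny] <- 0.25 * (U[1:nx, 1:(ny - 1), drop = FALSE] +
                            U[2:(nx + 1), 1:(ny - 1), drop = FALSE] +
                            U[1:nx, 2:ny, drop = FALSE] +
                            U[2:(nx + 1), 2:ny, drop = FALSE])
  }
  Dv_s <- pmax(Dv2, p$min_depth)
  EV <- -p$f * Ubar -
    Ubar * .upwind_dx(V, Ubar, dx) -
    V * .upwind_dy(V, V, dy) +
    tauy / (p$rho0 * Dv_s) +
    p$eddy_visc * .laplacian(V, dx, dy)
  cf2 <- g * sqrt(V^2 + Ubar^2) / (Dv_s * p$chezy^2)
  Dfr2 <- 1 + dt * cf2
  Vt <- (V + dt * EV) / Dfr2
  Vt[!ws$vact] <- 0
  gam2 <- (g * dt / dy) / Dfr2
  gam2[!ws$vact] <- 0
  lam2 <- Dv2 * gam2 * dt / (2 * dy)        # nx x (ny+1)

  qx2 <- (dt / 2) * Du2 * U
  xdiv <- (qx2[2:(nx + 1), , drop = FALSE] - qx2[1:nx, , drop = FALSE]) / dx
  rhs2 <- zs1 - xdiv -
    (dt / (2 * dy)) * (Dv2[, 2:(ny + 1), drop = FALSE] * Vt[, 2:(ny + 1), drop = FALSE] -
                       Dv2[, 1:ny, drop = FALSE] * Vt[, 1:ny, drop = FALSE])
  a2 <- -lam2[, 1:ny, drop = FALSE]
  b2 <- 1 + lam2[, 1:ny, drop = FALSE] + lam2[, 2:(ny + 1), drop = FALSE]
  c2 <- -lam2[, 2:(ny + 1), drop = FALSE]
  a2[fix] <- 0; c2[fix] <- 0; b2[fix] <- 1
  rhs2[ws$open] <- zb_full
  rhs2[!ws$wet] <- 0
  znew_t <- .tridiag_batch(t(a2), t(b2), t(c2), t(rhs2))
  znew_i <- t(znew_t)

  dzV <- matrix(0, nx, ny + 1)
  if (ny >= 2) {
    dzV[, 2:ny] <- znew_i[, 2:ny, drop = FALSE] - znew_i[, 1:(ny - 1), drop = FALSE]
  }
  V <- Vt - gam2 * dzV
  V[!ws$vact] <- 0
  qy2 <- (dt / 2) * Dv2 * V
  znew <- zs1 - xdiv -
    (qy2[, 2:(ny + 1), drop = FALSE] - qy2[, 1:ny, drop = FALSE]) / dy
  znew[ws$open] <- zb_full
  znew[!ws$wet] <- 0

  st$zeta <- znew
  st$U <- U
  st$V <- V
  st$qx <- qx1 + qx2
  st$qy <- qy1 + qy2
  st$t <- t0 + dt

  if (any(!is.finite(znew)) || any(!is.finite(U)) || any(!is.finite(V))) {
    bad <- which(!is.finite(znew), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- matrix(c(NA_integer_, NA_integer_), 1)
    .stopf("numerical instability at t = %.1f s (first bad cell i=%s, j=%s); reduce dt",
           st$t, bad[1, 1], bad[1, 2])
  }
  st
}

#' Advance the hydrodynamic state by one time step
#'
#' One ADI step of the depth-averaged shallow-water equations: continuity in
#' flux form, momentum with upwind advection, Coriolis, pressure gradient,
#' Chezy friction (implicit, on total depth floored at `min_depth`), wind
#' stress and horizontal eddy viscosity.  Zero normal flow at closed
#' boundaries; the water level at open-boundary cells is prescribed by
#' [boundary_elevation()].
#'
#' @param state a [hydro_state()]; @param grid a [bay_grid()];
#' @param params [hydro_params()]; @param forcing [make_default_forcing()].
#' @param ramp_s forcing ramp-up time (s); the boundary amplitude is scaled
#'   by `min(1, t/ramp_s)` to suppress start-up transients.
#' @return The advanced `hydro_state` (time `t + dt`).
#' @export
step_hydro <- function(state, grid, params, forcing, ramp_s = 0) {
  .step_hydro_core(state, .hydro_workspace(grid), params, forcing, ramp_s)
}

# cell-centre velocity components from the staggered faces
.centre_velocity <- function(st, nx, ny) {
  uc <- 0.5 * (st$U[1:nx, , drop = FALSE] + st$U[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (st$V[, 1:ny, drop = FALSE] + st$V[, 2:(ny + 1), drop = FALSE])
  list(u = uc, v = vc)
}

# flow direction "toward", degrees clockwise from +y (north), in [0, 360)
.flow_direction_deg <- function(u, v) (atan2(u, v) * 180 / pi) %% 360

#' Run the tidal hydrodynamic model
#'
#' Repeated [step_hydro()] for `duration_s` seconds, recording water level,
#' current speed and flow direction at the given stations.
#'
#' @inheritParams step_hydro
#' @param duration_s simulated duration (s), > 0.
#' @param stations named list of `c(i, j)` cell indices.
#' @param stride record every `stride`-th step.
#' @param quiet suppress the time-step advisory warning.
#' @return `hydro_run` list: final `state`, and `records` — per station a list
#'   of [obs_series()] for `level`, `speed` and `direction`.
#' @export
run_hydro <- function(grid, params, forcing, duration_s,
                      stations = list(), stride = 1L, ramp_s = 0,
                      quiet = FALSE) {
  if (!(duration_s > 0)) .stopf("duration_s must be positive")
  lim <- cfl_limit(grid, params)
  if (!quiet && params$dt > lim) {
    warning(sprintf(
      "dt = %.0f s exceeds the explicit-stability guide value %.1f s; the ADI scheme stays stable but accuracy may degrade",
      params$dt, lim), call. = FALSE)
  }
  ws <- .hydro_workspace(grid)
  st <- hydro_state(grid)
  nsteps <- ceiling(duration_s / params$dt)
  nrec <- floor(nsteps / stride)
  rec_t <- numeric(nrec)
  rec <- lapply(stations, function(s) {
    list(level = numeric(nrec), speed = numeric(nrec), direction = numeric(nrec))
  })
  k <- 0L
  for (n in seq_len(nsteps)) {
    st <- .step_hydro_core(st, ws, params, forcing, ramp_s)
    if (n %% stride == 0L) {
      k <- k + 1L
      rec_t[k] <- st$t
      if (length(stations) > 0) {
        cv <- .centre_velocity(st, ws$nx, ws$ny)
        for (s in seq_along(stations)) {
          i <- stations[[s]][1]; j <- stations[[s]][2]
          rec[[s]]$level[k] <- st$zeta[i, j]
          rec[[s]]$speed[k] <- sqrt(cv$u[i, j]^2 + cv$v[i, j]^2)
          rec[[s]]$direction[k] <- .flow_direction_deg(cv$u[i, j], cv$v[i, j])
        }
      }
    }
  }
  records <- lapply(seq_along(stations), function(s) {
    i <- stations[[s]][1]; j <- stations[[s]][2]
    list(level = obs_series(rec_t, rec[[s]]$level, "level", i, j),
         speed = obs_series(rec_t, rec[[s]]$speed, "speed", i, j),
         direction = obs_series(rec_t, rec[[s]]$direction, "direction", i, j))
  })
  names(records) <- names(stations)
  structure(list(state = st, records = records, grid = grid, params = params),
            class = "hydro_run")
}
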