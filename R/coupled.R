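# Coupled hydrodynamics + fate run on a shared clock, with station records,
# the time-averaged deposition field and an explicit mass ledger.

#' Run the coupled hydrodynamic / PAH fate simulation
#'
#' Alternates [step_hydro()] and [step_transport()] on a shared clock from
#' the hot-start initial condition, recording water level, current speed and
#' direction and PAH concentration at the stations, the time-averaged
#' deposition-rate field, and a cumulative mass ledger.
#'
#' @param grid a [bay_grid()]; @param hparams [hydro_params()];
#' @param forcing [make_default_forcing()]; @param fparams [fate_params()];
#' @param partition [phase_partition()]; @param ic [initial_condition()];
#' @param sources [source_set()] or NULL; @param duration_s duration (s);
#' @param stations named list of `c(i, j)`; @param stride record stride;
#' @param ramp_s boundary-forcing ramp (s); @param quiet suppress warnings.
#' @return `coupled_run` list: final `hydro` and `pah` states, `records`
#'   (per station: `level`, `speed`, `direction`, `concentration`
#'   [obs_series()]), `dep_mean` (time-mean deposition field, ng/(m^2 d)),
#'   `speed_mean` (time-mean current-speed field at the record instants, m/s),
#'   and `ledger` (data frame of cumulative masses in ng over time).
#' @export
run_coupled <- function(grid, hparams, forcing, fparams,
                        partition = phase_partition(),
                        ic = initial_condition(), sources = NULL,
                        duration_s, stations = list(), stride = 1L,
                        ramp_s = 0, quiet = TRUE) {
  if (!(duration_s > 0)) .stopf("duration_s must be positive")
  if (!quiet) {
    lim <- cfl_limit(grid, hparams)
    if (hparams$dt > lim) {
      warning(sprintf("dt = %.0f s exceeds the explicit-stability guide value %.1f s",
                      hparams$dt, lim), call. = FALSE)
    }
  }
  ws <- .hydro_workspace(grid)
  hyd <- hydro_state(grid)
  pah <- hot_start_init(grid, ic)
  Qmat <- NULL
  if (!is.null(sources) && nrow(sources) > 0) {
    Qmat <- matrix(0, grid$nx, grid$ny)
    for (k in seq_len(nrow(sources))) {
      Qmat[sources$i[k], sources$j[k]] <- Qmat[sources$i[k], sources$j[k]] + sources$Q[k]
    }
  }
  dt <- hparams$dt
  nsteps <- ceiling(duration_s / dt)
  nrec <- floor(nsteps / stride)
  rec_t <- numeric(nrec)
  rec <- lapply(stations, function(s) {
    list(level = numeric(nrec), speed = numeric(nrec),
         direction = numeric(nrec), concentration = numeric(nrec))
  })
  led_names <- c("adv_net", "source_in", "volatilized", "degraded", "bed_net")
  cum <- c(adv_net = 0, source_in = 0, volatilized = 0, degraded = 0, bed_net = 0)
  ledger <- matrix(0, nrec, length(led_names) + 2,
                   dimnames = list(NULL, c("time_s", "water_mass", led_names)))
  dep_sum <- matrix(0, grid$nx, grid$ny)
  speed_sum <- matrix(0, grid$nx, grid$ny)
  k <- 0L
  for (n in seq_len(nsteps)) {
    hyd <- .step_hydro_core(hyd, ws, hparams, forcing, ramp_s)
    pah <- .step_transport_core(pah, hyd, ws, fparams, partition, Qmat,
                                ic$c_outside, hparams$min_depth, dt)
    cum <- cum + attr(pah, "ledger")[led_names]
    dep_sum <- dep_sum + pah$dep_rate
    if (n %% stride == 0L) {
      k <- k + 1L
      rec_t[k] <- hyd$t
      ledger[k, ] <- c(hyd$t,
                       water_mass(pah, hyd, grid, hparams$min_depth),
                       cum)
      cv <- .centre_velocity(hyd, ws$nx, ws$ny)
      speed_sum <- speed_sum + sqrt(cv$u^2 + cv$v^2)
      if (length(stations) > 0) {
        for (s in seq_along(stations)) {
          i <- stations[[s]][1]; j <- stations[[s]][2]
          rec[[s]]$level[k] <- hyd$zeta[i, j]
          rec[[s]]$speed[k] <- sqrt(cv$u[i, j]^2 + cv$v[i, j]^2)
          rec[[s]]$direction[k] <- .flow_direction_deg(cv$u[i, j], cv$v[i, j])
          rec[[s]]$concentration[k] <- pah$C[i, j]
        }
      }
    }
  }
  records <- lapply(seq_along(stations), function(s) {
    i <- stations[[s]][1]; j <- stations[[s]][2]
    list(level = obs_series(rec_t, rec[[s]]$level, "level", i, j),
         speed = obs_series(rec_t, rec[[s]]$speed, "speed", i, j),
         direction = obs_series(rec_t, rec[[s]]$direction, "direction", i, j),
         concentration = obs_series(rec_t, rec[[s]]$concentration,
                                    "concentration", i, j))
  })
  names(records) <- names(stations)
  structure(
    list(hydro = hyd, pah = pah, records = records,
         dep_mean = dep_sum / nsteps,
         speed_mean = if (k > 0) speed_sum / k else speed_sum,
         ledger = as.data.frame(ledger),
         grid = grid, hparams = hparams, fparams = fparams),
    class = "coupled_run"
  )
}

#' @export
print.coupled_run <- function(x, ...) {
  cat(sprintf("<coupled_run> t = %.2f d on a %d x %d grid\n",
              x$pah$t / 86400, x$grid$nx, x$grid$ny))
  sea <- sea_cells(x$grid)
  cat(sprintf("  water C: %.3g-%.3g ng/L; bed: %.3g-%.3g ng/g; mean deposition %.3g ng/(m^2 d)\n",
              min(x$pah$C[sea]), max(x$pah$C[sea]),
              min(x$pah$C_sed[sea]), max(x$pah$C_sed[sea]),
              mean(x$dep_mean[sea])))
  invisible(x)
}

# Along-channel thirds of the interior sea cells (mouth / middle / head),
# used by the qualitative spatial-gradient analyses.
#' Split interior sea cells into along-channel thirds
#'
#' @param grid a [bay_grid()].
#' @return List of three logical matrices: `mouth`, `middle`, `head`.
#' @export
channel_thirds <- function(grid) {
  i <- row(grid$mask)
  sea <- sea_cells(grid)
  b1 <- grid$nx / 3
  b2 <- 2 * grid$nx / 3
  list(mouth = sea & i <= b1,
       middle = sea & i > b1 & i <= b2,
       head = sea & i > b2)
}
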