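# Model validation (Willmott skill with rating bands), dynamic-equilibrium
# detection and bounded coordinate-descent parameter calibration.

.skill_rating <- function(s) {
  # boundary values belong to the band below
  if (s <= 0.2) "poor" else if (s <= 0.5) "medium" else if (s <= 0.7) "good" else "excellent"
}

.ang_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}
.circ_mean_deg <- function(x) {
  r <- x * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

#' Willmott skill of a model series against observations
#'
#' `Skill = 1 - sum((M - D)^2) / sum((|M - Dbar| + |D - Dbar|)^2)` with
#' `Dbar = mean(D)`; 1 for a perfect match.  Rating bands: poor (<= 0.2),
#' medium (0.2, 0.5], good (0.5, 0.7], excellent (> 0.7).  For flow
#' direction, set `circular = TRUE`: deviations are then angular distances on
#' the circle (degrees) and `Dbar` is the circular mean.
#'
#' @param M model series ([obs_series()] or numeric).
#' @param D observed series, same length (n >= 2).
#' @param circular compare on the circle (for directions in degrees).
#' @return `skill_report`: list with `skill`, `rating`, `n`.
#' @export
willmott_skill <- function(M, D, circular = FALSE) {
  m <- if (inherits(M, "obs_series")) M$value else as.numeric(M)
  d <- if (inherits(D, "obs_series")) D$value else as.numeric(D)
  if (length(m) != length(d)) .stopf("series lengths differ")
  n <- length(d)
  if (n < 2) .stopf("at least 2 paired samples are required")
  if (circular) {
    dbar <- .circ_mean_deg(d)
    num <- sum(.ang_diff(m, d)^2)
    den <- sum((.ang_diff(m, dbar) + .ang_diff(d, dbar))^2)
  } else {
    dbar <- mean(d)
    num <- sum((m - d)^2)
    den <- sum((abs(m - dbar) + abs(d - dbar))^2)
  }
  if (den == 0) {
    if (num == 0) {
      s <- 1  # degenerate perfect agreement on a constant series
    } else {
      .stopf("skill undefined: observations carry no variability but model deviates")
    }
  } else {
    s <- 1 - num / den
  }
  structure(list(skill = s, rating = .skill_rating(s), n = n),
            class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf("Willmott skill = %.4f (%s), n = %d\n", x$skill, x$rating, x$n))
  invisible(x)
}

#' Time to dynamic equilibrium of a concentration series
#'
#' Splits the series into consecutive windows of length `window_s` and
#' returns the earliest window boundary `t*` after which the window mean
#' changes by less than `tol` (relatively) across `k` consecutive windows.
#' `NA` if the series never stabilizes.
#'
#' @param series an [obs_series()] (or list with `time_s`, `value`).
#' @param window_s window length (s), > 0.
#' @param tol relative tolerance on the window-mean change, > 0.
#' @param k number of consecutive quiet window transitions required, >= 1.
#' @return Time `t*` (s), or `NA_real_`.
#' @export
equilibration_time <- function(series, window_s, tol, k = 3) {
  if (!(window_s > 0 && tol > 0 && k >= 1)) {
    .stopf("window_s and tol must be positive and k >= 1")
  }
  tt <- series$time_s
  vv <- series$value
  w <- floor(max(tt) / window_s)
  if (w < k + 1) .stopf("series spans fewer than k + 1 = %d full windows", k + 1)
  idx <- pmin(floor((tt - 1e-9) / window_s) + 1, w)
  keep <- tt <= w * window_s & tt > 0
  means <- tapply(vv[keep], idx[keep], mean)
  means <- as.numeric(means)
  for (w0 in seq_len(w - k)) {
    prev <- means[w0 + seq_len(k) - 1]
    nxt <- means[w0 + seq_len(k)]
    rel <- abs(nxt - prev) / pmax(abs(prev), .Machine$double.eps)
    if (all(rel < tol)) return(w0 * window_s)
  }
  NA_real_
}

#' Calibration specification
#'
#' @param params data frame with columns `name`, `lower`, `upper`,
#'   `n_trials` (>= 2); parameters are scanned in row order.
#' @param objective `"max_skill"` (Willmott skill, maximized) or
#'   `"min_rmse"`.
#' @param passes number of coordinate-descent passes.
#' @return `calibration_spec` list.
#' @export
calibration_spec <- function(params, objective = c("max_skill", "min_rmse"),
                             passes = 1L) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(params),
            all(c("name", "lower", "upper", "n_trials") %in% names(params)))
  if (any(params$lower >= params$upper)) .stopf("lower bounds must be < upper bounds")
  if (any(params$n_trials < 2)) .stopf("each parameter needs at least 2 trials")
  structure(list(params = params, objective = objective,
                 passes = as.integer(passes)),
            class = "calibration_spec")
}

#' Calibrate model parameters by bounded coordinate descent
#'
#' Scans each parameter in the declared order over `n_trials` evenly spaced
#' values within its bounds, holding the others at their incumbent values
#' (midpoints initially), and moves the incumbent to the scan optimum when it
#' improves the objective.  One full pass by default.  Ties break toward the
#' lower parameter value.  Forward-run failures are recorded in the trace and
#' skipped.
#'
#' @param spec a [calibration_spec()].
#' @param obs observed series ([obs_series()] or numeric vector).
#' @param forward deterministic function of a named parameter vector
#'   returning the model series aligned with `obs`.
#' @return `calibration_result`: `best` (named vector), `objective` (the
#'   optimum, skill or RMSE), `trace` (data frame: trial, the parameter
#'   vector, `objective`, `ok`), `n_evaluations`.
#' @export
calibrate <- function(spec, obs, forward) {
  stopifnot(inherits(spec, "calibration_spec"))
  obs_v <- if (inherits(obs, "obs_series")) obs$value else as.numeric(obs)
  pr <- spec$params
  theta <- setNames((pr$lower + pr$upper) / 2, pr$name)
  maximize <- spec$objective == "max_skill"
  eval_obj <- function(model) {
    mv <- if (inherits(model, "obs_series")) model$value else as.numeric(model)
    if (maximize) willmott_skill(mv, obs_v)$skill else sqrt(mean((mv - obs_v)^2))
  }
  best_obj <- if (maximize) -Inf else Inf
  trace <- vector("list", spec$passes * sum(pr$n_trials))
  trial <- 0L
  n_ok <- 0L
  for (pass in seq_len(spec$passes)) {
    for (r in seq_len(nrow(pr))) {
      vals <- seq(pr$lower[r], pr$upper[r], length.out = pr$n_trials[r])
      scan_obj <- rep(if (maximize) -Inf else Inf, length(vals))
      for (v in seq_along(vals)) {
        trial <- trial + 1L
        th <- theta
        th[pr$name[r]] <- vals[v]
        obj <- tryCatch(eval_obj(forward(th)), error = function(e) {
          warning(sprintf("forward run failed at trial %d (%s = %g): %s",
                          trial, pr$name[r], vals[v], conditionMessage(e)),
                  call. = FALSE)
          NA_real_
        })
        if (is.finite(obj)) {
          n_ok <- n_ok + 1L
          scan_obj[v] <- obj
        }
        trace[[trial]] <- data.frame(trial = trial, t(th), objective = obj,
                                     ok = is.finite(obj))
      }
      if (any(is.finite(scan_obj))) {
        # ascending scan + strict comparison => ties resolve to the lower value
        v_best <- if (maximize) which.max(scan_obj) else which.min(scan_obj)
        improves <- if (maximize) scan_obj[v_best] > best_obj else scan_obj[v_best] < best_obj
        if (improves) {
          best_obj <- scan_obj[v_best]
          theta[pr$name[r]] <- vals[v_best]
        }
      }
    }
  }
  if (n_ok == 0L) .stopf("calibration failed: every forward run errored")
  structure(list(best = theta, objective = best_obj,
                 trace = do.call(rbind, trace), n_evaluations = trial),
            class = "calibration_result")
}

#' Coupled-model forward closure for calibration
#'
#' Builds the deterministic forward map used to calibrate the five
#' field-adjustable parameters against a station concentration series.  The
#' scanned values use the conventional printed scales: `Ve` is the kinematic
#' viscosity in 1e-6 m^2/s, `Psi` a Manning-type roughness converted to the
#' Chezy coefficient via `C = H_mean^(1/6) / Psi`, `kg`/`kl` the film
#' transfer coefficients (m/d) and `Dsw` the water-seabed diffusion
#' coefficient (m^2/d).
#'
#' @param grid a [bay_grid()]; @param hparams,forcing,fparams,partition,ic,
#'   sources as in [run_coupled()]; @param station `c(i, j)` of the
#'   calibration station; @param duration_s forward-run duration (s);
#' @param stride record stride; @param ramp_s forcing ramp (s).
#' @return Function of a named vector (any subset of `Ve`, `Psi`, `kg`,
#'   `kl`, `Dsw`) returning the station concentration [obs_series()].
#' @export
calibration_forward <- function(grid, hparams, forcing, fparams,
                                partition = phase_partition(),
                                ic = initial_condition(), sources = NULL,
                                station, duration_s, stride = 6L,
                                ramp_s = 0) {
  hmean <- mean(grid$H[wet_cells(grid)])
  function(theta) {
    hp <- hparams
    fp <- fparams
    if ("Psi" %in% names(theta)) hp$chezy <- hmean^(1 / 6) / theta[["Psi"]]
    if ("Ve" %in% names(theta)) fp$Ve <- theta[["Ve"]] * 1e-6
    if ("kg" %in% names(theta)) fp$k_g <- theta[["kg"]]
    if ("kl" %in% names(theta)) fp$k_l <- theta[["kl"]]
    if ("Dsw" %in% names(theta)) fp$D_sw <- theta[["Dsw"]]
    run <- run_coupled(grid, hp, forcing, fp, partition, ic, sources,
                       duration_s = duration_s,
                       stations = list(st = station), stride = stride,
                       ramp_s = ramp_s)
    run$records$st$concentration
  }
}
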