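# Tidal forcing: harmonic synthesis of the open-boundary water level from a
# set of named constituents, plus synthetic station observations.

# Periods (hours) of the supported constituents, from standard tidal theory.
.TIDAL_PERIOD_H <- c(
  M2 = 12.4206012,
  S2 = 12.0,
  N2 = 12.65834751,
  K2 = 11.96723606,
  K1 = 23.93446959,
  O1 = 25.81933871,
  P1 = 24.06588766,
  Q1 = 26.86835677,
  M1 = 24.84120241
)

#' Tidal constituent frequencies
#'
#' Canonical angular frequencies (rad/s) of the supported tidal constituents.
#' @return Named numeric vector over `r paste(names(.TIDAL_PERIOD_H), collapse = ", ")`.
#' @export
tidal_frequencies <- function() 2 * pi / (.TIDAL_PERIOD_H * 3600)

#' Construct tidal forcing from amplitude and phase maps
#'
#' Builds a `tidal_forcing` object with the canonical angular frequency of
#' each named constituent.  Constituents present in `amplitudes` but absent
#' from `phases` get phase 0 (and vice versa, amplitude 0).
#'
#' @param amplitudes named numeric vector of amplitudes (m), names from the
#'   supported set (see [tidal_frequencies()]).
#' @param phases named numeric vector of phases (rad).
#' @return `tidal_forcing`: data frame with columns `name`, `omega` (rad/s),
#'   `amplitude` (m), `phase` (rad).
#' @examples
#' make_default_forcing(c(M2 = 1.0, S2 = 0.4))
#' @export
make_default_forcing <- function(amplitudes = numeric(), phases = numeric()) {
  nm <- union(names(amplitudes), names(phases))
  freqs <- tidal_frequencies()
  unknown <- setdiff(nm, names(freqs))
  if (length(unknown) > 0) {
    .stopf("unknown tidal constituent(s): %s (supported: %s)",
           paste(unknown, collapse = ", "),
           paste(names(freqs), collapse = ", "))
  }
  amp <- vapply(nm, function(n) if (n %in% names(amplitudes)) amplitudes[[n]] else 0, 0)
  ph <- vapply(nm, function(n) if (n %in% names(phases)) phases[[n]] else 0, 0)
  if (any(amp < 0)) .stopf("tidal amplitudes must be non-negative")
  f <- data.frame(name = nm, omega = unname(freqs[nm]),
                  amplitude = unname(amp), phase = unname(ph),
                  stringsAsFactors = FALSE)
  class(f) <- c("tidal_forcing", "data.frame")
  f
}

#' Water level at the open boundary
#'
#' Harmonic synthesis `sum_k a_k cos(omega_k t - phi_k)`.
#'
#' @param forcing a [make_default_forcing()] object.
#' @param t time(s) in seconds since simulation start (vectorized).
#' @return Elevation (m); 0 for empty forcing.
#' @export
boundary_elevation <- function(forcing, t) {
  if (nrow(forcing) == 0) return(rep(0, length(t)))
  z <- numeric(length(t))
  for (k in seq_len(nrow(forcing))) {
    z <- z + forcing$amplitude[k] * cos(forcing$omega[k] * t - forcing$phase[k])
  }
  z
}

#' Station observation series
#'
#' A tidy container for observed or simulated station time series: the CSV
#' dialect has columns `time_s`, `quantity`, `station_i`, `station_j`,
#' `value`.
#'
#' @param time_s numeric, strictly increasing times (s since start).
#' @param value numeric, finite values (level m, speed m/s, direction deg, or
#'   concentration ng/L).
#' @param quantity one of `"level"`, `"speed"`, `"direction"`,
#'   `"concentration"` (free-form allowed).
#' @param station_i,station_j cell index of the station.
#' @return `obs_series`, a data frame.
#' @export
obs_series <- function(time_s, value, quantity = "level",
                       station_i = NA_integer_, station_j = NA_integer_) {
  if (length(time_s) != length(value)) .stopf("time_s and value lengths differ")
  if (length(time_s) == 0) .stopf("series must be non-empty")
  if (any(diff(time_s) <= 0)) .stopf("times must be strictly increasing")
  if (any(!is.finite(value))) .stopf("values must be finite")
  s <- data.frame(time_s = time_s, quantity = quantity,
                  station_i = station_i, station_j = station_j,
                  value = value, stringsAsFactors = FALSE)
  class(s) <- c("obs_series", "data.frame")
  s
}

#' Synthesize noisy pseudo-observations from a model truth series
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `noise_sd`
#' to the truth values.  The RNG state of the caller is left untouched; the
#' same `(truth, noise_sd, seed)` always reproduces the same series.
#'
#' @param truth an [obs_series()] (or numeric vector of values).
#' @param noise_sd noise standard deviation (same units as the values), >= 0.
#' @param seed integer seed.
#' @return Same shape as `truth`, with perturbed values.
#' @export
synthesize_observations <- function(truth, noise_sd, seed) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    .stopf("noise_sd must be a single non-negative number")
  }
  vals <- if (inherits(truth, "obs_series")) truth$value else as.numeric(truth)
  if (length(vals) == 0) .stopf("truth must be non-empty")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  noisy <- vals + rnorm(length(vals), mean = 0, sd = noise_sd)
  if (inherits(truth, "obs_series")) {
    out <- truth
    out$value <- noisy
    out
  } else {
    noisy
  }
}
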