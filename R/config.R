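# Run configuration: a nested key-value tree (YAML on disk) mirroring every
# parameter of the model, with defaults applied on load and every value
# validated through the owning constructor.

#' Default run configuration
#'
#' The full nested parameter tree of the pipeline with its default study
#' conditions: a 60 x 20 idealized narrow bay (30 km x 6 km, 25 m at the
#' mouth shoaling to 5 m at the head), mixed semidiurnal/diurnal forcing
#' (M2, S2, K1, O1), one head-adjacent shoreline source, and the kinetic,
#' calibration and exposure parameters.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    grid = list(nx = 60L, ny = 20L, length_m = 30000, width_m = 6000,
                depth_mouth_m = 25, depth_head_m = 5),
    forcing = list(
      amplitudes = list(M2 = 0.9, S2 = 0.3, K1 = 0.3, O1 = 0.25),
      phases = list(M2 = 0, S2 = 0, K1 = 0, O1 = 0)
    ),
    hydro = list(g = 9.81, rho0 = 1024.2,
                 f = 2 * 7.292115e-5 * sin(39.4 * pi / 180),
                 chezy = 45, CD = 0.0013, rhoA = 1.225,
                 wind_speed = 0, wind_dir = 0,
                 eddy_visc = 10.1, dt = 300, min_depth = 0.1),
    fate = list(sigma_tx = 10.1, sigma_ty = 10.1, k_l = 4.15, k_g = 0.76,
                a1 = 10.89, a2 = -4000, C_equ = 5, Tem = 15, P = 101325,
                Ng = 42, Rg = 8.314, phi = 0.45, D_sw = 0.014, L_sw = 1,
                K0 = 0.003, K1 = 0.017, Kt = 1, omega = 0.45, rhoT = 1600,
                d_p = 5e-6, Ve = 1.5e-6, rho0 = 1024.2, g = 9.81,
                rho_b = 1.3, L_sed = 0.1,
                flux_vol_const = 0, flux_atm_const = 0),
    partition = list(organics = 0.30, organism = 0.15,
                     dissolved = 0.10, particulate = 0.45),
    ic = list(c_inside = 50, c_outside = 10, csed_init = 5),
    sources = list(list(i = 58L, j = 2L, Q = 1.2e8)),
    stations = list(mouth = list(i = 4L, j = 10L),
                    mid = list(i = 30L, j = 10L),
                    head = list(i = 57L, j = 10L)),
    run = list(duration_days = 60, record_stride = 6L, ramp_hours = 12),
    calibration = list(
      station = "mid", duration_days = 2, objective = "max_skill",
      passes = 1L,
      params = list(
        list(name = "Psi", lower = 0.02, upper = 0.06, n_trials = 48L),
        list(name = "Ve", lower = 1.44, upper = 1.57, n_trials = 7L),
        list(name = "Dsw", lower = 0.012, upper = 0.015, n_trials = 3L),
        list(name = "kg", lower = 0.73, upper = 0.78, n_trials = 9L),
        list(name = "kl", lower = 4.12, upper = 4.19, n_trials = 12L)
      )
    ),
    risk = list(EF = 350, ED = 40, IR = 100, SA = 5700, AF = 0.07,
                ABS = 0.13, AT = 70 * 365, BW = 70,
                CSF_ing = 7.3, CSF_derm = 3.85, PEF = 1.36e9,
                profile = "uniform"),
    seed = 1L,
    outdir = "bayfate-out"
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

# sections that are user-enumerated collections: replaced wholesale, never
# key-merged with the defaults
.REPLACE_KEYS <- c(".forcing.amplitudes", ".forcing.phases", ".stations",
                   ".sources", ".calibration.params", ".risk.profile")

# recursive merge of user values into defaults; unknown keys are rejected
.merge_config <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (path %in% .REPLACE_KEYS) return(user)
  if (!is.list(user) || !is.list(default)) return(user)
  if (is.null(names(default)) || is.null(names(user))) return(user)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0) {
    .stopf("unknown configuration key(s): %s",
           paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in names(user)) {
    default[[k]] <- .merge_config(default[[k]], user[[k]], paste0(path, ".", k))
  }
  default
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, merges it over [default_run_config()] (unknown keys
#' are rejected), and validates every section through its owning
#' constructor, so an invariant violation is reported with the failing key.
#' An empty file yields the defaults.
#'
#' @param path YAML file path.
#' @return Validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(default_run_config(), user)
  class(cfg) <- c("run_config", "list")
  config_objects(cfg)  # validation side effect
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg a `run_config`; @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Materialize the model objects described by a configuration
#'
#' @param cfg a `run_config`.
#' @return List with `grid`, `forcing`, `hparams`, `fparams`, `partition`,
#'   `ic`, `sources`, `stations`, plus run settings.
#' @export
config_objects <- function(cfg) {
  grid <- do.call(build_idealized_bay, cfg$grid)
  forcing <- make_default_forcing(unlist(cfg$forcing$amplitudes),
                                  unlist(cfg$forcing$phases))
  hparams <- do.call(hydro_params, cfg$hydro)
  fparams <- do.call(fate_params, cfg$fate)
  partition <- do.call(phase_partition, cfg$partition)
  ic <- do.call(initial_condition, cfg$ic)
  src <- if (length(cfg$sources) > 0) {
    source_set(i = vapply(cfg$sources, `[[`, 0L, "i"),
               j = vapply(cfg$sources, `[[`, 0L, "j"),
               Q = vapply(cfg$sources, `[[`, 0, "Q"),
               grid = grid)
  } else {
    source_set()
  }
  stations <- lapply(cfg$stations, function(s) c(s$i, s$j))
  for (nm in names(stations)) {
    s <- stations[[nm]]
    if (s[1] < 1 || s[1] > grid$nx || s[2] < 1 || s[2] > grid$ny) {
      .stopf("station '%s' at (%d, %d) lies outside the %d x %d grid",
             nm, s[1], s[2], grid$nx, grid$ny)
    }
  }
  list(grid = grid, forcing = forcing, hparams = hparams, fparams = fparams,
       partition = partition, ic = ic, sources = src, stations = stations,
       duration_s = cfg$run$duration_days * 86400,
       stride = cfg$run$record_stride,
       ramp_s = cfg$run$ramp_hours * 3600,
       seed = cfg$seed)
}

#' Calibration spec and forward map from a configuration
#'
#' @param cfg a `run_config`; @param objs optionally the pre-built
#'   [config_objects()].
#' @return List with `spec` ([calibration_spec()]) and `forward`
#'   ([calibration_forward()] closure at the configured station).
#' @export
config_calibration <- function(cfg, objs = config_objects(cfg)) {
  pr <- do.call(rbind, lapply(cfg$calibration$params, function(p) {
    data.frame(name = p$name, lower = p$lower, upper = p$upper,
               n_trials = p$n_trials, stringsAsFactors = FALSE)
  }))
  spec <- calibration_spec(pr, objective = cfg$calibration$objective,
                           passes = cfg$calibration$passes)
  fwd <- calibration_forward(
    objs$grid, objs$hparams, objs$forcing, objs$fparams, objs$partition,
    objs$ic, objs$sources,
    station = objs$stations[[cfg$calibration$station]],
    duration_s = cfg$calibration$duration_days * 86400,
    stride = objs$stride, ramp_s = objs$ramp_s
  )
  list(spec = spec, forward = fwd)
}
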