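# File I/O: station series CSV (time_s, quantity, station_i, station_j,
# value), long-format gridded field CSV (i, j, x, y, value) and the mass
# ledger CSV.

#' Read and write station observation series
#'
#' The CSV dialect has columns `time_s`, `quantity`, `station_i`,
#' `station_j`, `value`.  `write_obs_csv` accepts a single [obs_series()] or
#' a list of them (rows are concatenated).
#'
#' @param x an [obs_series()] or list of them; @param path file path.
#' @export
write_obs_csv <- function(x, path) {
  if (inherits(x, "obs_series")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_obs_csv
#' @return `read_obs_csv`: a list of [obs_series()], one per (quantity,
#'   station) combination.
#' @export
read_obs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "quantity", "station_i", "station_j", "value")
  if (!all(need %in% names(df))) {
    .stopf("observation CSV must have columns: %s", paste(need, collapse = ", "))
  }
  key <- paste(df$quantity, df$station_i, df$station_j, sep = "_")
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), ]
    obs_series(d$time_s, d$value, d$quantity[1], d$station_i[1], d$station_j[1])
  })
}

#' Write a gridded field as long-format CSV
#'
#' Self-describing long format: one row per cell with indices, physical
#' cell-centre coordinates and the value; land cells are skipped.
#'
#' @param field numeric matrix on the grid; @param grid a [bay_grid()];
#' @param path file path; @param name value-column name.
#' @export
write_field_csv <- function(field, grid, path, name = "value") {
  wet <- which(wet_cells(grid), arr.ind = TRUE)
  df <- data.frame(i = wet[, 1], j = wet[, 2],
                   x = (wet[, 1] - 0.5) * grid$dx,
                   y = (wet[, 2] - 0.5) * grid$dy,
                   value = field[wet])
  names(df)[5] <- name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the outputs of a coupled run to a directory
#'
#' Writes the effective configuration (when given), the station series, the
#' final concentration / bed / time-mean deposition fields, the mass ledger
#' and the risk map.
#'
#' @param run a [run_coupled()] result; @param dir output directory;
#' @param cfg optional `run_config` echoed beside the outputs;
#' @param risk_params an [ilcr_params()].
#' @return The directory, invisibly.
#' @export
write_run_outputs <- function(run, dir, cfg = NULL, risk_params = ilcr_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg)) write_run_config(cfg, file.path(dir, "effective_config.yaml"))
  series <- unlist(run$records, recursive = FALSE, use.names = FALSE)
  if (length(series) > 0) write_obs_csv(series, file.path(dir, "stations.csv"))
  write_field_csv(run$pah$C, run$grid, file.path(dir, "concentration.csv"), "C_ng_L")
  write_field_csv(run$pah$C_sed, run$grid, file.path(dir, "bed_concentration.csv"), "Csed_ng_g")
  write_field_csv(run$dep_mean, run$grid, file.path(dir, "deposition_mean.csv"), "dep_ng_m2_d")
  utils::write.csv(run$ledger, file.path(dir, "mass_ledger.csv"),
                   row.names = FALSE, quote = FALSE)
  rm <- risk_map(sediment_teq(run$pah$C_sed), risk_params, run$grid)
  utils::write.csv(as.data.frame(rm), file.path(dir, "risk_map.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
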