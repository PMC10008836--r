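# Plain-text interchange: forcing and observation series as CSV with
# ISO-8601 time columns and unit-annotated headers, trajectories as tidy
# CSV.

FORCING_HEADERS <- c(time = "time",
                     sst = "sst_degC",
                     par0 = "par0_mol_photons_m2_d",
                     mld = "mld_m",
                     kappa = "kappa_per_d",
                     deep_no3 = "deep_no3_umol_kg",
                     deep_si = "deep_si_umol_kg",
                     deep_fe = "deep_fe_nmol_kg")

#' Write / read a forcing series as CSV
#'
#' ISO-8601 `time` column and unit-annotated headers
#' (`sst_degC`, `par0_mol_photons_m2_d`, `mld_m`, `kappa_per_d`,
#' `deep_*`).
#'
#' @param forcing A `forcing_series`.
#' @param path File path.
#' @return `read_forcing_csv()` returns a `forcing_series`.
#' @export
write_forcing_csv <- function(forcing, path) {
  stopifnot(inherits(forcing, "forcing_series"))
  out <- as.data.frame(forcing)[names(FORCING_HEADERS)]
  names(out) <- unname(FORCING_HEADERS)
  out$time <- format(out$time, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(unname(FORCING_HEADERS), names(df))
  if (length(missing))
    stop(sprintf("forcing CSV lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[unname(FORCING_HEADERS)]
  names(df) <- names(FORCING_HEADERS)
  df$time <- as.Date(df$time)
  new_forcing_series(df)
}

#' Write / read an observation series as CSV
#'
#' Columns `time` (ISO-8601) and `chl_obs_mg_m3`; gaps are empty cells.
#'
#' @param obs An `obs_series`.
#' @param path File path.
#' @return `read_obs_csv()` returns an `obs_series`.
#' @export
write_obs_csv <- function(obs, path) {
  stopifnot(inherits(obs, "obs_series"))
  out <- data.frame(time = format(obs$time, "%Y-%m-%d"),
                    chl_obs_mg_m3 = obs$chl_obs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_obs_csv
#' @export
read_obs_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "chl_obs_mg_m3") %in% names(df)))
    stop("observation CSV needs columns 'time' and 'chl_obs_mg_m3'",
         call. = FALSE)
  structure(data.frame(time = as.Date(df$time), chl_obs = df$chl_obs_mg_m3),
            class = c("obs_series", "data.frame"))
}

#' Write a trajectory as tidy CSV
#'
#' One row per time step and group; see
#' [as.data.frame.pft_trajectory()].
#'
#' @param traj A `pft_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df$time <- format(df$time, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
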