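# Internal helpers shared across modules.

PFT_NAMES <- c("diatoms", "coccolithophores", "chlorophytes",
               "dinoflagellates", "cyanobacteria", "phaeocystis")

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded generators do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# day-of-year on a 365.25-day cycle, used by the seasonal generator
day_of_year <- function(time) {
  as.numeric(time - as.Date(format(time, "%Y-01-01"))) + 1
}

# calendar month (1..12) of a Date vector
month_of <- function(time) as.integer(format(time, "%m"))

# first day of the calendar month of each Date (used as monthly key)
month_floor <- function(time) as.Date(format(time, "%Y-%m-01"))

# AR(1) red-noise series, zero mean, unit marginal variance approx
red_noise <- function(n, phi = 0.9) {
  innov <- rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}
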