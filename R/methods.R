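# S3 methods for the trajectory container.

#' @export
print.pft_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("pft_trajectory: %d steps (%s to %s), dt = %g d\n",
              n, x$time[1], x$time[n], x$dt))
  if (any(x$diagnostics$assimilated))
    cat(sprintf("  %d assimilation ticks\n",
                sum(x$diagnostics$assimilated)))
  cat(sprintf("  final total Chl %.3f mg m-3; final NO3 %.2f, Si %.2f umol/kg, Fe %.3f nmol/kg\n",
              x$chl_tot[n], x$no3[n], x$si[n], x$fe[n]))
  invisible(x)
}

#' Summarize a model trajectory
#'
#' Reports the range of total chlorophyll, the mean biomass fraction of
#' each group and the nutrient pools over the run.
#'
#' @param object A `pft_trajectory`.
#' @param ... Unused.
#' @return A list with `chl_tot_range`, `mean_fractions`,
#'   `nutrient_means`, invisibly printed.
#' @export
summary.pft_trajectory <- function(object, ...) {
  fr <- biomass_fractions(object)
  out <- list(chl_tot_range = range(object$chl_tot),
              mean_fractions = colMeans(fr, na.rm = TRUE),
              nutrient_means = c(no3 = mean(object$no3),
                                 nh4 = mean(object$nh4),
                                 si = mean(object$si),
                                 fe = mean(object$fe)))
  cat(sprintf("Total chlorophyll: %.3f to %.3f mg m-3\n",
              out$chl_tot_range[1], out$chl_tot_range[2]))
  cat("Mean biomass fractions:\n")
  print(round(out$mean_fractions, 3))
  cat("Mean nutrient pools (umol/kg; Fe nmol/kg):\n")
  print(round(out$nutrient_means, 3))
  invisible(out)
}

#' Plot a model trajectory
#'
#' Two stacked panels: total and per-group chlorophyll, and the nutrient
#' pools.
#'
#' @param x A `pft_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pft_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  cols <- c("blue", "red", "green3", "magenta", "cyan3", "black")
  graphics::matplot(x$time, cbind(x$chl_tot, x$chl), type = "l", lty = 1,
                    col = c("grey40", cols), xlab = "", xaxt = "n",
                    ylab = "Chl (mg m-3)", ...)
  graphics::axis.Date(1, x$time)
  graphics::legend("topright", c("total", colnames(x$chl)), lty = 1,
                   col = c("grey40", cols), cex = 0.6, bty = "n")
  graphics::matplot(x$time, cbind(x$no3, x$nh4, x$si, 10 * x$fe),
                    type = "l", lty = 1,
                    col = c("blue", "purple", "orange", "red"),
                    xlab = "", xaxt = "n", ylab = "Nutrients")
  graphics::axis.Date(1, x$time)
  graphics::legend("topright",
                   c("NO3", "NH4", "Si (umol/kg)", "Fe x10 (nmol/kg)"),
                   lty = 1, col = c("blue", "purple", "orange", "red"),
                   cex = 0.6, bty = "n")
  invisible(x)
}

#' Tidy data frame view of a trajectory
#'
#' Long format: one row per time step and group for the per-group fields,
#' with the scalar state and light diagnostics repeated per row.
#'
#' @param x A `pft_trajectory`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.pft_trajectory <- function(x, ...) {
  nt <- length(x$time)
  data.frame(time = rep(x$time, times = 6),
             pft = rep(colnames(x$chl), each = nt),
             chl = as.vector(x$chl),
             mu = as.vector(x$diagnostics$mu),
             f_nut = as.vector(x$diagnostics$f_nut),
             f_e = as.vector(x$diagnostics$f_e),
             binding = as.vector(x$diagnostics$binding),
             w = as.vector(x$diagnostics$w),
             chl_tot = rep(x$chl_tot, 6),
             no3 = rep(x$no3, 6), nh4 = rep(x$nh4, 6),
             si = rep(x$si, 6), fe = rep(x$fe, 6),
             gamma = rep(x$diagnostics$gamma, 6),
             kd490 = rep(x$diagnostics$kd490, 6),
             kd_par = rep(x$diagnostics$kd_par, 6),
             e_ml = rep(x$diagnostics$e_ml, 6),
             assimilated = rep(x$diagnostics$assimilated, 6))
}
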