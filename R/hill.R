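#' Split a titration into low and high ligand-concentration regions
#'
#' The binding isotherm is analysed separately in the two saturation
#' regimes. Injections with ligand mole fraction \code{xB <= threshold}
#' form the low region; the remainder form the high region. Each side
#' must retain at least 3 points for a Hill fit to be identifiable.
#'
#' @param series a \code{titration_series}.
#' @param threshold mole-fraction boundary in (0, 1); default 0.5.
#' @return list with elements \code{low} and \code{high}, each a
#'   \code{titration_series}.
#' @export
split_regions <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 6L) stop("need at least 6 injections to split")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  xB <- mole_fractions(series$ligand_uM)$xB
  lo <- xB <= threshold
  if (sum(lo) < 3L || sum(!lo) < 3L)
    stop(sprintf("degenerate split at threshold %g: %d low / %d high points",
                 threshold, sum(lo), sum(!lo)))
  sub <- function(keep) {
    out <- series[keep, , drop = FALSE]
    attributes(out)[c("design", "truth", "seed", "heat_unit")] <-
      attributes(series)[c("design", "truth", "seed", "heat_unit")]
    class(out) <- class(series)
    out
  }
  list(low = sub(lo), high = sub(!lo))
}

# internal: profiled Hill sum of squares. Given (n, Kd) the saturation
# theta = L^n/(Kd^n + L^n) enters linearly through q_max.
hill_profile <- function(n, logKd, L, q) {
  t1 <- exp(n * (log(L) - logKd))   # (L/Kd)^n, stable for extreme Kd
  theta <- t1 / (1 + t1)
  denom <- sum(theta^2)
  if (denom == 0) return(list(ssr = sum(q^2), q_max = 0, theta = theta))
  q_max <- sum(q * theta) / denom
  list(ssr = sum((q - q_max * theta)^2), q_max = q_max, theta = theta)
}

#' Fit the Hill equation to one titration region
#'
#' Least-squares fit of \code{q = q_max * L^n / (Kd^n + L^n)} with L the
#' molar ligand concentration. The saturation heat enters linearly, so
#' the objective is profiled down to (n, log Kd) and minimised by
#' Nelder-Mead from a small multi-start grid over n; Ka is reported as
#' 1/Kd. The Hill coefficient is constrained to [0.1, 10] and a fit
#' pinned at either bound is flagged with a warning.
#'
#' Derived thermodynamics use \code{\link{thermodynamics}} at the series
#' temperature. The binding enthalpy defaults to the fitted saturation
#' heat taken as molar (flagged via \code{dH_from_qmax}); supply
#' \code{dH} explicitly when a calibrated molar enthalpy is available.
#'
#' @param series a \code{titration_series} (a region from
#'   \code{\link{split_regions}} or a full series).
#' @param region label stored with the fit, e.g. \code{"low"} or
#'   \code{"high"}.
#' @param dH optional molar binding enthalpy (kJ/mol) for the derived
#'   thermodynamics.
#' @param starts starting values for the Hill coefficient.
#' @return object of class \code{"hill_fit"} with fields \code{n},
#'   \code{Ka} (L/mol), \code{Kd}, \code{q_max}, \code{region},
#'   \code{thermo}, and diagnostics.
#' @export
fit_hill <- function(series, region = "all", dH = NULL,
                     starts = c(0.5, 1, 2, 4)) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 3L) stop("need at least 3 points for a Hill fit")
  q <- series$heat
  if (diff(range(q)) == 0) stop("heats are all equal; nothing to fit")
  L <- series$ligand_uM * 1e-6   # mol/L
  n_lo <- 0.1; n_hi <- 10
  obj <- function(par) {
    n <- par[1]
    if (n < n_lo || n > n_hi) return(1e30)
    hill_profile(n, par[2], L, q)$ssr
  }
  logKd0 <- mean(log(L))
  runs <- lapply(starts, function(n0) {
    o <- optim(c(n0, logKd0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    # polish with a second pass from the candidate optimum
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    o
  })
  ssrs <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(ssrs)]]
  n_hat <- best$par[1]; logKd <- best$par[2]
  if (abs(n_hat - n_lo) < 1e-6 || abs(n_hat - n_hi) < 1e-6)
    warning("Hill coefficient pinned at its bound [0.1, 10]")
  prof <- hill_profile(n_hat, logKd, L, q)
  Kd <- exp(logKd)
  temperature <- attr(series, "design")$temperature
  if (is.null(temperature)) temperature <- 300
  dH_from_qmax <- is.null(dH)
  if (dH_from_qmax) dH <- prof$q_max
  out <- list(n = n_hat, Ka = 1 / Kd, Kd = Kd, q_max = prof$q_max,
              region = region,
              thermo = thermodynamics(1 / Kd, dH, temperature),
              dH_from_qmax = dH_from_qmax,
              fitted.values = prof$q_max * prof$theta,
              residuals = q - prof$q_max * prof$theta,
              ssr = prof$ssr, series = series)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s region)\n", x$region))
  cat(sprintf("  n     = %.4g  (%s cooperativity)\n", x$n,
              classify_cooperativity(x$n)))
  cat(sprintf("  Ka    = %.4g L/mol   (Kd = %.4g mol/L)\n", x$Ka, x$Kd))
  cat(sprintf("  q_max = %.4g\n", x$q_max))
  if (x$dH_from_qmax)
    cat("  (dH taken from fitted q_max; supply dH for calibrated values)\n")
  print(x$thermo)
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...)
  c(n = object$n, Ka = object$Ka, q_max = object$q_max)

#' @export
predict.hill_fit <- function(object, ligand_uM = NULL, ...) {
  if (is.null(ligand_uM)) return(object$fitted.values)
  L <- ligand_uM * 1e-6
  object$q_max * L^object$n / (object$Kd^object$n + L^object$n)
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
plot.hill_fit <- function(x, ...) {
  L <- x$series$ligand_uM
  plot(L, x$series$heat, log = "x", xlab = "ligand (umol/L)",
       ylab = "heat", pch = 2, ...)
  grid_uM <- exp(seq(log(min(L)), log(max(L)), length.out = 200))
  lines(grid_uM, predict(x, grid_uM))
  invisible(x)
}

#' Classify binding cooperativity
#'
#' Labels a Hill coefficient n or cooperativity parameter p as
#' \code{"positive"} (> 1 + epsilon), \code{"negative"} (< 1 - epsilon)
#' or \code{"non-cooperative"} otherwise.
#'
#' @param value positive Hill coefficient or cooperativity parameter.
#' @param epsilon half-width of the non-cooperative band (default 0.05).
#' @return character label.
#' @export
classify_cooperativity <- function(value, epsilon = 0.05) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0,
            epsilon >= 0)
  if (value > 1 + epsilon) "positive"
  else if (value < 1 - epsilon) "negative"
  else "non-cooperative"
}

#' Two-region Hill analysis of a titration
#'
#' Convenience wrapper: splits the titration at \code{threshold} and fits
#' the Hill equation in each region.
#'
#' @inheritParams split_regions
#' @param ... passed to \code{\link{fit_hill}}.
#' @return list with \code{low} and \code{high} \code{hill_fit} objects.
#' @export
hill_two_region <- function(series, threshold = 0.5, ...) {
  parts <- split_regions(series, threshold)
  list(low = fit_hill(parts$low, region = "low", ...),
       high = fit_hill(parts$high, region = "high", ...))
}
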