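#' Reversible-inhibition rate laws
#'
#' Closed-form steady-state velocities for the classical reversible
#' inhibition mechanisms:
#' \describe{
#'   \item{none}{\code{v = Vmax*S/(Km + S)} (plain Michaelis-Menten; I ignored)}
#'   \item{competitive}{\code{v = Vmax*S/(Km*(1 + I/Ki) + S)}}
#'   \item{noncompetitive}{\code{v = Vmax*S/((Km + S)*(1 + I/Ki))}}
#'   \item{uncompetitive}{\code{v = Vmax*S/(Km + S*(1 + I/Ki))}}
#'   \item{mixed}{\code{v = Vmax*S/(Km*(1 + I/Ki) + S*(1 + I/(alpha*Ki)))}}
#' }
#' For pure noncompetitive inhibition, I = Ki halves every velocity and
#' the S -> Inf limit is \code{Vmax/(1 + I/Ki)}.
#'
#' @param mechanism one of \code{"none"}, \code{"competitive"},
#'   \code{"noncompetitive"}, \code{"uncompetitive"}, \code{"mixed"}.
#' @param Vmax maximal velocity (> 0).
#' @param Km Michaelis constant, mM (> 0).
#' @param S substrate concentrations, mM.
#' @param I inhibitor concentrations, uM (recycled with S).
#' @param Ki inhibition constant, uM.
#' @param alpha mixed-mechanism factor (> 0); 1 recovers noncompetitive.
#' @return numeric vector of velocities.
#' @export
rate_law <- function(mechanism, Vmax, Km, S, I = 0, Ki = Inf, alpha = 1) {
  mechanism <- match.arg(mechanism,
                         c("none", "competitive", "noncompetitive",
                           "uncompetitive", "mixed"))
  stopifnot(Vmax > 0, Km > 0, all(S > 0), all(I >= 0), Ki > 0, alpha > 0)
  switch(mechanism,
         none = Vmax * S / (Km + S),
         competitive = Vmax * S / (Km * (1 + I / Ki) + S),
         noncompetitive = Vmax * S / ((Km + S) * (1 + I / Ki)),
         uncompetitive = Vmax * S / (Km + S * (1 + I / Ki)),
         mixed = Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / (alpha * Ki))))
}

#' Lineweaver-Burk analysis of a rate grid
#'
#' For each inhibitor level, ordinary least squares of 1/v on 1/S. The
#' apparent kinetic constants are read from the line: slope = Km_app /
#' Vmax_app, intercept = 1/Vmax_app, x-intercept = -1/Km_app. Rows with
#' nonpositive velocity are excluded with a warning.
#'
#' @param dataset a \code{kinetics_dataset} or data.frame with columns
#'   \code{substrate_mM}, \code{inhibitor_uM}, \code{velocity}.
#' @return object of class \code{"lb_lines"}: a data.frame with one row
#'   per inhibitor level (\code{inhibitor_uM}, \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{Km_app}, \code{Vmax_app},
#'   \code{x_intercept}).
#' @export
lineweaver_burk <- function(dataset) {
  stopifnot(all(c("substrate_mM", "inhibitor_uM", "velocity") %in%
                  names(dataset)))
  bad <- dataset$velocity <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive velocities excluded from the ",
            "double-reciprocal analysis")
    dataset <- dataset[!bad, , drop = FALSE]
  }
  levels_I <- sort(unique(dataset$inhibitor_uM))
  rows <- lapply(levels_I, function(I) {
    d <- dataset[dataset$inhibitor_uM == I, , drop = FALSE]
    if (length(unique(d$substrate_mM)) < 3L)
      stop(sprintf("inhibitor level %g uM has fewer than 3 substrate levels", I))
    fit <- lm(I(1 / velocity) ~ I(1 / substrate_mM), data = d)
    cf <- coef(fit)
    y <- 1 / d$velocity
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
    data.frame(inhibitor_uM = I, slope = unname(cf[2]),
               intercept = unname(cf[1]), r_squared = r2,
               Km_app = unname(cf[2] / cf[1]),
               Vmax_app = unname(1 / cf[1]),
               x_intercept = unname(-cf[1] / cf[2]))
  })
  structure(do.call(rbind, rows), class = c("lb_lines", "data.frame"))
}

#' @export
plot.lb_lines <- function(x, dataset = NULL, ...) {
  xlim <- c(min(0, min(x$x_intercept)) * 1.2, NA)
  smax <- if (is.null(dataset)) 1 else 1 / min(dataset$substrate_mM)
  s <- seq(min(0, min(x$x_intercept)) * 1.2, smax, length.out = 50)
  ymax <- max(x$intercept + x$slope * max(s))
  plot(NA, xlim = range(s), ylim = c(0, ymax), xlab = "1/[S] (1/mM)",
       ylab = "1/v", ...)
  for (i in seq_len(nrow(x)))
    abline(x$intercept[i], x$slope[i], lty = i)
  abline(h = 0, v = 0, col = "grey")
  legend("topleft", legend = sprintf("[I] = %g uM", x$inhibitor_uM),
         lty = seq_len(nrow(x)), bty = "n")
  invisible(x)
}

#' Classify the inhibition mechanism from Lineweaver-Burk lines
#'
#' Compares apparent Km and Vmax at each nonzero inhibitor level against
#' the uninhibited line: Km constant with Vmax decreasing is
#' noncompetitive; Vmax constant with Km increasing is competitive; both
#' decreasing in the same proportion is uncompetitive; Vmax decreasing
#' with Km increasing is mixed. Patterns that fit none of these (for
#' example noise-dominated grids or poorly determined lines) return
#' \code{"indeterminate"} rather than a guess.
#'
#' @param lines an \code{lb_lines} object including the I = 0 level.
#' @param rel_tol relative tolerance for "constant" and "equal"
#'   comparisons (default 0.15).
#' @return mechanism label: \code{"none"}, \code{"competitive"},
#'   \code{"noncompetitive"}, \code{"uncompetitive"}, \code{"mixed"} or
#'   \code{"indeterminate"}.
#' @export
classify_mechanism <- function(lines, rel_tol = 0.15) {
  stopifnot(inherits(lines, "data.frame"), rel_tol > 0)
  if (nrow(lines) < 2L)
    stop("need at least 2 inhibitor levels (including 0) to classify")
  if (min(lines$inhibitor_uM) != 0)
    stop("mechanism classification requires an uninhibited (I = 0) level")
  base <- lines[lines$inhibitor_uM == 0, ]
  rest <- lines[lines$inhibitor_uM > 0, , drop = FALSE]
  kmr <- rest$Km_app / base$Km_app
  vmr <- rest$Vmax_app / base$Vmax_app
  top <- which.max(rest$inhibitor_uM)
  km_const <- all(abs(kmr - 1) <= rel_tol)
  vm_const <- all(abs(vmr - 1) <= rel_tol)
  km_up <- kmr[top] > 1 + rel_tol
  vm_down <- vmr[top] < 1 - rel_tol
  proportional <- all(abs(kmr - vmr) <= rel_tol * pmax(vmr, kmr))
  if (km_const && vm_const) "none"
  else if (km_const && vm_down) "noncompetitive"
  else if (vm_const && km_up) "competitive"
  else if (vm_down && kmr[top] < 1 - rel_tol && proportional) "uncompetitive"
  else if (vm_down && km_up) "mixed"
  else "indeterminate"
}

#' Fit a reversible-inhibition model to a rate grid
#'
#' Global weighted nonlinear least squares on the untransformed
#' velocities (Levenberg-Marquardt): the primary estimator is never the
#' double-reciprocal regression, which only supplies starting values,
#' diagnostics and the secondary-plot cross-check. With
#' \code{mechanism = "auto"} the mechanism is first classified from the
#' Lineweaver-Burk apparent parameters.
#'
#' For mechanisms with an inhibition constant, the secondary plot
#' (LB slope for competitive/mixed, 1/Vmax_app for
#' noncompetitive/uncompetitive, regressed on [I]; x-intercept -Ki) is
#' reported alongside as \code{Ki_secondary}; on noise-free data the two
#' routes agree to optimizer tolerance.
#'
#' @param dataset a \code{kinetics_dataset}.
#' @param mechanism mechanism label or \code{"auto"}.
#' @param rel_tol classification tolerance passed to
#'   \code{\link{classify_mechanism}}.
#' @return object of class \code{"inhibition_fit"}: \code{mechanism},
#'   \code{Vmax}, \code{Km} (mM), \code{Ki} (uM), \code{alpha},
#'   \code{Ki_secondary}, residual norm and convergence flag.
#' @export
fit_inhibition <- function(dataset, mechanism = "auto", rel_tol = 0.15) {
  stopifnot(all(c("substrate_mM", "inhibitor_uM", "velocity") %in%
                  names(dataset)))
  lines <- lineweaver_burk(dataset)
  if (identical(mechanism, "auto")) {
    mechanism <- classify_mechanism(lines, rel_tol)
    if (mechanism == "indeterminate")
      stop("mechanism could not be classified from the data; ",
           "specify it explicitly")
  }
  mechanism <- match.arg(mechanism,
                         c("none", "competitive", "noncompetitive",
                           "uncompetitive", "mixed"))
  base <- lines[which.min(lines$inhibitor_uM), ]
  Vmax0 <- max(base$Vmax_app, 1e-8)
  Km0 <- max(base$Km_app, 1e-8)
  d <- dataset

  if (mechanism == "none") {
    fit <- minpack.lm::nlsLM(
      velocity ~ Vmax * substrate_mM / (Km + substrate_mM), data = d,
      start = list(Vmax = Vmax0, Km = Km0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15))
    cf <- coef(fit)
    out <- list(mechanism = mechanism, Vmax = cf[["Vmax"]], Km = cf[["Km"]],
                Ki = NA_real_, alpha = NA_real_, Ki_secondary = NA_real_,
                residual = sqrt(sum(residuals(fit)^2)),
                converged = fit$convInfo$isConv, lb = lines, fit = fit)
    class(out) <- "inhibition_fit"
    return(out)
  }

  # secondary-plot Ki: x-intercept of the [I]-linear apparent quantity
  sec_y <- switch(mechanism,
                  competitive = lines$slope,
                  mixed = lines$slope,
                  noncompetitive = lines$intercept,
                  uncompetitive = lines$intercept)
  sec <- lm(sec_y ~ lines$inhibitor_uM)
  Ki_secondary <- unname(coef(sec)[1] / coef(sec)[2])
  Ki0 <- if (is.finite(Ki_secondary) && Ki_secondary > 0) Ki_secondary
         else max(dataset$inhibitor_uM) / 2

  form <- switch(mechanism,
    competitive = velocity ~ Vmax * substrate_mM /
      (Km * (1 + inhibitor_uM / Ki) + substrate_mM),
    noncompetitive = velocity ~ Vmax * substrate_mM /
      ((Km + substrate_mM) * (1 + inhibitor_uM / Ki)),
    uncompetitive = velocity ~ Vmax * substrate_mM /
      (Km + substrate_mM * (1 + inhibitor_uM / Ki)),
    mixed = velocity ~ Vmax * substrate_mM /
      (Km * (1 + inhibitor_uM / Ki) +
         substrate_mM * (1 + inhibitor_uM / (alpha * Ki))))
  start <- list(Vmax = Vmax0, Km = Km0, Ki = Ki0)
  lower <- c(1e-12, 1e-12, 1e-12)
  if (mechanism == "mixed") {
    start$alpha <- 1
    lower <- c(lower, 1e-6)
  }
  fit <- minpack.lm::nlsLM(
    form, data = d, start = start, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- coef(fit)
  Ki_hat <- cf[["Ki"]]
  if (Ki_hat <= 1.01e-12)
    warning("fitted Ki pinned at its lower bound; estimate unreliable")
  out <- list(mechanism = mechanism, Vmax = cf[["Vmax"]], Km = cf[["Km"]],
              Ki = Ki_hat,
              alpha = if (mechanism == "mixed") cf[["alpha"]] else 1,
              Ki_secondary = Ki_secondary,
              residual = sqrt(sum(residuals(fit)^2)),
              converged = fit$convInfo$isConv, lb = lines, fit = fit)
  class(out) <- "inhibition_fit"
  out
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Reversible inhibition fit\n")
  cat("  mechanism:", x$mechanism, "\n")
  cat(sprintf("  Vmax = %.6g,  Km = %.6g mM\n", x$Vmax, x$Km))
  if (!is.na(x$Ki)) {
    cat(sprintf("  Ki   = %.6g uM (global fit)\n", x$Ki))
    cat(sprintf("  Ki   = %.6g uM (secondary plot)\n", x$Ki_secondary))
  }
  if (!is.na(x$alpha) && x$mechanism == "mixed")
    cat(sprintf("  alpha = %.4g\n", x$alpha))
  cat(sprintf("  residual norm: %.4g; converged: %s\n",
              x$residual, x$converged))
  invisible(x)
}

#' @export
coef.inhibition_fit <- function(object, ...) {
  c(Vmax = object$Vmax, Km = object$Km, Ki = object$Ki,
    alpha = object$alpha)
}

#' @export
predict.inhibition_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object$fit))
  rate_law(object$mechanism, Vmax = object$Vmax, Km = object$Km,
           S = newdata$substrate_mM, I = newdata$inhibitor_uM,
           Ki = if (is.na(object$Ki)) Inf else object$Ki,
           alpha = if (is.na(object$alpha)) 1 else object$alpha)
}

#' @export
residuals.inhibition_fit <- function(object, ...) residuals(object$fit)

#' Estimate IC50 from a dose-response curve
#'
#' Two-parameter logistic fit in log-concentration:
#' \code{activity = 1 / (1 + (I/ic50)^slope)}, fitted by
#' Levenberg-Marquardt on the points with I > 0 (the model already
#' passes through activity 1 at I = 0). The data must cross
#' half-maximal activity; a grid that does not span roughly [0.2, 0.8]
#' triggers an identifiability warning.
#'
#' @param dose_response a \code{dose_response} data.frame
#'   (\code{inhibitor_uM}, \code{activity}).
#' @return object of class \code{"ic50_fit"}: \code{ic50} (uM),
#'   \code{slope}, standard errors and a 95\% confidence interval on
#'   ic50 from the residual variance.
#' @export
estimate_ic50 <- function(dose_response) {
  stopifnot(all(c("inhibitor_uM", "activity") %in% names(dose_response)))
  d <- dose_response[dose_response$inhibitor_uM > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 positive-dose points")
  if (min(d$activity) >= 0.5 || max(d$activity) <= 0.5)
    stop("activities do not cross 0.5; IC50 is not identifiable")
  if (min(d$activity) > 0.2 || max(d$activity) < 0.8)
    warning("activities do not span [0.2, 0.8]; IC50 may be poorly ",
            "determined")
  i0 <- which.min(abs(d$activity - 0.5))
  fit <- minpack.lm::nlsLM(
    activity ~ 1 / (1 + exp(slope * (log(inhibitor_uM) - log_ic50))),
    data = d,
    start = list(log_ic50 = log(d$inhibitor_uM[i0]), slope = 1),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  ic50 <- exp(cf[["log_ic50"]])
  ci <- ic50 * exp(c(-1, 1) * 1.96 * se[1])
  out <- list(ic50 = ic50, slope = cf[["slope"]],
              ic50_ci95 = ci, se_log_ic50 = se[1], se_slope = se[2],
              residual = sqrt(sum(residuals(fit)^2)), fit = fit,
              data = dose_response)
  class(out) <- "ic50_fit"
  out
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("Dose-response logistic fit\n")
  cat(sprintf("  IC50  = %.6g uM  (95%% CI %.4g - %.4g)\n",
              x$ic50, x$ic50_ci95[1], x$ic50_ci95[2]))
  cat(sprintf("  slope = %.4g\n", x$slope))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...)
  c(ic50 = object$ic50, slope = object$slope)

#' @export
predict.ic50_fit <- function(object, inhibitor_uM = NULL, ...) {
  if (is.null(inhibitor_uM)) inhibitor_uM <- object$data$inhibitor_uM
  1 / (1 + (inhibitor_uM / object$ic50)^object$slope)
}

#' Test inhibition reversibility from enzyme-dilution lines
#'
#' For each inhibitor level, regresses velocity on enzyme concentration;
#' reversible inhibition gives straight lines through the origin, so the
#' test is that every |intercept| is at most \code{tol} times the
#' largest observed velocity.
#'
#' @param enzyme_conc positive enzyme concentrations (any unit).
#' @param velocities matrix (or data.frame) with one column per
#'   inhibitor level and one row per enzyme concentration.
#' @param tol intercept tolerance as a fraction of max velocity
#'   (default 0.05).
#' @return list with \code{reversible} (logical), and per-level
#'   \code{intercepts} and \code{slopes}.
#' @export
reversibility_check <- function(enzyme_conc, velocities, tol = 0.05) {
  velocities <- as.matrix(velocities)
  stopifnot(all(enzyme_conc > 0), nrow(velocities) == length(enzyme_conc))
  if (length(enzyme_conc) < 3L)
    stop("need at least 3 enzyme concentrations per inhibitor level")
  fits <- apply(velocities, 2, function(v) coef(lm(v ~ enzyme_conc)))
  intercepts <- fits[1, ]
  list(reversible = all(abs(intercepts) <= tol * max(abs(velocities))),
       intercepts = intercepts, slopes = fits[2, ])
}
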