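#' Construct the extended solvation parameter set
#'
#' Bundles the four parameters of the extended solvation model of ITC
#' binding heats: the cooperativity parameter \code{p} (unitless; p > 1
#' indicates positive cooperativity), the saturation heat \code{q_max}
#' (heat units of the titration), and the solvation indices \code{delta_A}
#' (low-saturation environment) and \code{delta_B} (high-saturation
#' environment), both unitless.
#'
#' @param p positive cooperativity parameter.
#' @param q_max saturation heat (same units as the observed heats).
#' @param delta_A,delta_B solvation indices (unitless, any sign).
#' @return An object of class \code{"solvation_parameters"}.
#' @export
solvation_parameters <- function(p, q_max, delta_A, delta_B) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p), p > 0,
            is.numeric(q_max), length(q_max) == 1L, is.finite(q_max),
            is.numeric(delta_A), length(delta_A) == 1L, is.finite(delta_A),
            is.numeric(delta_B), length(delta_B) == 1L, is.finite(delta_B))
  structure(list(p = p, q_max = q_max, delta_A = delta_A, delta_B = delta_B),
            class = "solvation_parameters")
}

#' @export
print.solvation_parameters <- function(x, ...) {
  cat("Extended solvation model parameters\n")
  cat(sprintf("  p       = %.6g  (%s cooperativity)\n", x$p,
              classify_cooperativity(x$p)))
  cat(sprintf("  q_max   = %.6g\n", x$q_max))
  cat(sprintf("  delta_A = %.6g\n  delta_B = %.6g\n", x$delta_A, x$delta_B))
  invisible(x)
}

#' Mole fractions of bound ligand along a titration
#'
#' The ligand mole fraction is defined against the largest cumulative
#' ligand concentration reached in the titration:
#' \code{xB[i] = L[i] / max(L)}, \code{xA = 1 - xB}.
#'
#' @param ligand_conc numeric vector of cumulative ligand concentrations
#'   (strictly increasing), or a \code{titration_series}.
#' @return A data.frame with columns \code{xA}, \code{xB}.
#' @export
mole_fractions <- function(ligand_conc) {
  if (inherits(ligand_conc, "titration_series")) ligand_conc <- ligand_conc$ligand_uM
  stopifnot(is.numeric(ligand_conc), length(ligand_conc) >= 1L,
            all(is.finite(ligand_conc)), all(ligand_conc >= 0))
  if (max(ligand_conc) <= 0) stop("all ligand concentrations are zero")
  xB <- ligand_conc / max(ligand_conc)
  data.frame(xA = 1 - xB, xB = xB)
}

#' Cooperative bound fraction
#'
#' Transforms the raw ligand mole fraction \code{xB} into the cooperative
#' bound fraction \code{xB' = p*xB / (xA + p*xB)} with \code{xA = 1 - xB}.
#' For \code{p = 1} this is the identity; it is strictly increasing in
#' \code{p} for fixed \code{xB} in (0,1) and preserves the endpoints 0, 1.
#'
#' @param xB numeric vector in [0, 1].
#' @param p positive cooperativity parameter.
#' @return numeric vector \code{xB'} in [0, 1].
#' @export
cooperative_fraction <- function(xB, p) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p <= 0) stop("cooperativity parameter p must be > 0")
  stopifnot(all(xB >= 0 & xB <= 1))
  p * xB / ((1 - xB) + p * xB)
}

#' Forward heat prediction under the extended solvation model
#'
#' Evaluates, per injection,
#' \deqn{q = q_{max} x'_B - (\delta_A x'_A + \delta_B x'_B)\,
#'           (x'_A L_A + x'_B L_B)}
#' where \code{xA' = 1 - xB'} is the cooperative free fraction and
#' \code{LA}, \code{LB} are the relative partial molar dilution enthalpies
#' of the two solvation environments. With \code{LA = LB = 0} (no dilution
#' data) the model reduces to \code{q = q_max * xB'}.
#'
#' @param params a \code{solvation_parameters} object.
#' @param xB raw ligand mole fractions in [0, 1].
#' @param LA,LB dilution enthalpy vectors (recycled scalars allowed).
#' @return numeric vector of predicted heats.
#' @export
predict_heats <- function(params, xB, LA = 0, LB = 0) {
  stopifnot(inherits(params, "solvation_parameters"))
  n <- length(xB)
  if (length(LA) == 1L) LA <- rep(LA, n)
  if (length(LB) == 1L) LB <- rep(LB, n)
  if (length(LA) != n || length(LB) != n)
    stop("xB, LA and LB must have equal length")
  xbp <- cooperative_fraction(xB, params$p)
  xap <- 1 - xbp
  env <- xap * LA + xbp * LB
  params$q_max * xbp - (params$delta_A * xap + params$delta_B * xbp) * env
}

#' Relative partial molar dilution enthalpies by the tangent method
#'
#' From a dilution-heat series \code{q_dil(xB)} the two partial molar
#' quantities are read off the tangent line at each grid point:
#' \code{LA = q - xB * dq/dxB} (intercept at xB = 0) and
#' \code{LB = q + (1 - xB) * dq/dxB} (intercept at xB = 1). The derivative
#' is taken by central finite differences on the interior and one-sided
#' differences at the ends.
#'
#' @param dilution a \code{dilution_series} (see
#'   \code{\link{simulate_dilution}}) or a data.frame with columns
#'   \code{xB}, \code{q_dilut}.
#' @return data.frame with columns \code{xB}, \code{LA}, \code{LB}.
#' @export
partial_molar_dilution <- function(dilution) {
  xB <- dilution$xB
  q <- dilution$q_dilut
  stopifnot(length(xB) == length(q))
  if (length(xB) < 3L) stop("need at least 3 dilution grid points")
  if (any(diff(xB) <= 0)) stop("xB grid must be strictly increasing")
  n <- length(xB)
  d <- numeric(n)
  d[1] <- (q[2] - q[1]) / (xB[2] - xB[1])
  d[n] <- (q[n] - q[n - 1]) / (xB[n] - xB[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (q[i + 1] - q[i - 1]) / (xB[i + 1] - xB[i - 1])
  }
  data.frame(xB = xB, LA = q - xB * d, LB = q + (1 - xB) * d)
}

# internal: profiled residual machinery for the solvation fit.
# Given p the model is linear in (q_max, delta_A, delta_B):
#   q = q_max*xbp - delta_A*(xap*env) - delta_B*(xbp*env),  env = xap*LA+xbp*LB
# so each trial p costs one linear least-squares solve.
solvation_design <- function(p, xB, LA, LB) {
  xbp <- cooperative_fraction(xB, p)
  xap <- 1 - xbp
  env <- xap * LA + xbp * LB
  cbind(q_max = xbp, delta_A = -xap * env, delta_B = -xbp * env)
}

solvation_profile <- function(p, xB, heat, LA, LB, reduced) {
  X <- solvation_design(p, xB, LA, LB)
  if (reduced) X <- X[, 1L, drop = FALSE]
  fit <- lm.fit(X, heat)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(ssr = sum(fit$residuals^2), beta = beta)
}

#' Fit the extended solvation model to a titration
#'
#' Least-squares estimation of (p, q_max, delta_A, delta_B) from
#' per-injection heats. Because the model is linear in everything but p,
#' the sum of squares is profiled: for each trial p the remaining three
#' parameters are solved exactly by linear least squares, and p itself is
#' optimised in one dimension (Brent) from several starting brackets.
#' Ties between converged starts are broken by lowest residual, then
#' lowest p.
#'
#' When the dilution enthalpies are identically zero the solvation indices
#' multiply a zero regressor and are unidentifiable; the fit then drops to
#' the reduced model \code{q = q_max * xB'} and reports
#' \code{delta_A = delta_B = 0} with \code{reduced = TRUE}.
#'
#' @param series a \code{titration_series}.
#' @param LA,LB dilution enthalpy vectors aligned with the injections;
#'   defaults to the series' own \code{LA}/\code{LB} columns, else 0.
#' @param starts numeric vector of starting values for p (multi-start).
#' @return An object of class \code{"solvation_fit"}: the parameter
#'   estimates, residual norm, per-start diagnostics, and the model form
#'   string actually fitted.
#' @export
fit_solvation <- function(series, LA = NULL, LB = NULL,
                          starts = c(0.5, 1, 2, 5)) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 5L) stop("need at least 5 injections to fit")
  heat <- series$heat
  if (!all(is.finite(heat))) stop("heats must be finite")
  if (is.null(LA)) LA <- if ("LA" %in% names(series)) series$LA else 0
  if (is.null(LB)) LB <- if ("LB" %in% names(series)) series$LB else 0
  n <- nrow(series)
  if (length(LA) == 1L) LA <- rep(LA, n)
  if (length(LB) == 1L) LB <- rep(LB, n)
  xB <- mole_fractions(series$ligand_uM)$xB
  reduced <- all(LA == 0) && all(LB == 0)

  lp_lo <- log(1e-3); lp_hi <- log(1e3)
  obj <- function(lp) solvation_profile(exp(lp), xB, heat, LA, LB, reduced)$ssr
  # one local descent per start, plus a coarse-grid safeguard against
  # profile multimodality
  lp_grid <- seq(lp_lo, lp_hi, length.out = 121)
  grid_best <- lp_grid[which.min(vapply(lp_grid, obj, numeric(1)))]
  runs <- lapply(c(starts, exp(grid_best)), function(p0) {
    o <- tryCatch(
      nlminb(log(p0), obj, lower = lp_lo, upper = lp_hi,
             control = list(abs.tol = 0, rel.tol = 1e-14,
                            x.tol = 1e-14, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(o)) return(NULL)
    list(p = exp(o$par), ssr = o$objective, convergence = o$convergence,
         start = p0)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L)
    stop("solvation fit failed to converge from every start")
  ssrs <- vapply(runs, `[[`, numeric(1), "ssr")
  ps <- vapply(runs, `[[`, numeric(1), "p")
  best <- order(ssrs, ps)[1L]
  # high-precision polish in a tight bracket around the winner
  lp_b <- log(ps[best])
  span <- diff(lp_grid[1:2])
  pol <- optimize(obj, c(max(lp_lo, lp_b - span), min(lp_hi, lp_b + span)),
                  tol = 1e-12)
  p_hat <- if (pol$objective <= ssrs[best]) exp(pol$minimum) else ps[best]
  prof <- solvation_profile(p_hat, xB, heat, LA, LB, reduced)
  beta <- prof$beta
  q_max <- unname(beta["q_max"])
  dA <- if (reduced) 0 else unname(beta["delta_A"])
  dB <- if (reduced) 0 else unname(beta["delta_B"])
  params <- solvation_parameters(p_hat, q_max, dA, dB)
  fitted <- predict_heats(params, xB, LA, LB)
  out <- list(
    parameters = params,
    fitted.values = fitted,
    residuals = heat - fitted,
    ssr = prof$ssr,
    sigma = sqrt(prof$ssr / max(1, n - (if (reduced) 2 else 4))),
    reduced = reduced,
    starts = data.frame(start = vapply(runs, `[[`, numeric(1), "start"),
                        p = ps, ssr = ssrs),
    series = series, LA = LA, LB = LB, xB = xB,
    model = paste("q = q_max*xB' - (delta_A*xA' + delta_B*xB')",
                  "* (xA'*LA + xB'*LB)"))
  class(out) <- "solvation_fit"
  out
}

#' @export
print.solvation_fit <- function(x, ...) {
  cat("Extended solvation model fit\n")
  cat("  form:", x$model, "\n")
  if (x$reduced)
    cat("  (reduced model: LA = LB = 0, solvation indices fixed at 0)\n")
  print(x$parameters)
  cat(sprintf("  residual sum of squares: %.6g over %d injections\n",
              x$ssr, nrow(x$series)))
  invisible(x)
}

#' @export
coef.solvation_fit <- function(object, ...) {
  with(object$parameters,
       c(p = p, q_max = q_max, delta_A = delta_A, delta_B = delta_B))
}

#' @export
fitted.solvation_fit <- function(object, ...) object$fitted.values

#' @export
residuals.solvation_fit <- function(object, ...) object$residuals

#' @export
predict.solvation_fit <- function(object, xB = NULL, LA = NULL, LB = NULL, ...) {
  if (is.null(xB)) return(object$fitted.values)
  if (is.null(LA)) LA <- 0
  if (is.null(LB)) LB <- 0
  predict_heats(object$parameters, xB, LA, LB)
}

#' @export
summary.solvation_fit <- function(object, ...) {
  cf <- coef(object)
  cat("Extended solvation model fit summary\n")
  print(round(cf, 6))
  cat(sprintf("residual standard error: %.4g\n", object$sigma))
  cat("cooperativity:", classify_cooperativity(cf["p"]), "\n")
  cat("multi-start profile:\n")
  print(object$starts, row.names = FALSE)
  invisible(object)
}

#' @export
plot.solvation_fit <- function(x, ...) {
  plot(x$xB, x$series$heat, xlab = "ligand mole fraction xB",
       ylab = "heat per injection", pch = 2, ...)
  ord <- order(x$xB)
  lines(x$xB[ord], x$fitted.values[ord])
  invisible(x)
}

#' Association constant from a fitted solvation model
#'
#' Estimates Ka (L/mol) from the cooperative bound fraction along the
#' titration: at each usable injection
#' \code{Ka_i = xB'_i / ((1 - xB'_i) * Lfree_i)} with the free ligand
#' concentration approximated by total ligand minus a single-site bound
#' estimate \code{xB' * [E]}. The reported Ka is the median over
#' mid-titration injections (those with xB' inside \code{window}); the
#' window and per-injection values are returned for inspection. This
#' estimator is a documented package choice; other conventions exist.
#'
#' @param series a \code{titration_series} (concentrations in umol/L).
#' @param params fitted \code{solvation_parameters}.
#' @param window keep injections with xB' in this open interval
#'   (default c(0.1, 0.9)); saturated points are always excluded.
#' @return list with \code{Ka} (L/mol), \code{per_injection} data.frame,
#'   and the estimator description.
#' @export
association_constant <- function(series, params, window = c(0.1, 0.9)) {
  stopifnot(inherits(series, "titration_series"),
            inherits(params, "solvation_parameters"))
  xB <- mole_fractions(series$ligand_uM)$xB
  xbp <- cooperative_fraction(xB, params$p)
  E_uM <- attr(series, "design")$cell_enzyme_conc
  if (is.null(E_uM)) E_uM <- 0
  Lfree_uM <- pmax(series$ligand_uM - xbp * E_uM, .Machine$double.eps)
  Lfree_M <- Lfree_uM * 1e-6
  ka_i <- xbp / ((1 - xbp) * Lfree_M)
  use <- xbp > window[1] & xbp < window[2] & xbp < 1
  if (!any(use)) stop("no usable mid-titration injections for Ka estimation")
  list(Ka = stats::median(ka_i[use]),
       per_injection = data.frame(xB_prime = xbp, Ka = ka_i, used = use),
       estimator = sprintf(
         "median of xB'/((1-xB')*Lfree) over injections with xB' in (%g, %g)",
         window[1], window[2]))
}

#' Binding thermodynamics from an association constant
#'
#' Computes \code{dG = -R*T*ln(Ka)} in kJ/mol (R = 8.314 J mol^-1 K^-1)
#' and the entropic term \code{TdS = dH - dG}, which holds exactly by
#' construction for every object returned.
#'
#' @param Ka association constant, L/mol (> 0).
#' @param dH binding enthalpy, kJ/mol.
#' @param temperature absolute temperature, K (default 300, the ITC
#'   convention used throughout).
#' @return An object of class \code{"thermo_result"} with fields
#'   \code{Ka}, \code{dH}, \code{dG}, \code{TdS}, \code{temperature},
#'   all energies in kJ/mol.
#' @seealso \code{\link{ka_from_energy}} for the inverse map.
#' @export
thermodynamics <- function(Ka, dH, temperature = 300) {
  stopifnot(is.numeric(Ka), length(Ka) == 1L, is.finite(Ka))
  if (Ka <= 0) stop("Ka must be positive")
  stopifnot(temperature > 0, is.finite(dH))
  dG <- -GAS_CONSTANT_SI * temperature * log(Ka) / 1000
  structure(list(Ka = Ka, dH = dH, dG = dG, TdS = dH - dG,
                 temperature = temperature),
            class = "thermo_result")
}

#' Invert the free energy relation back to Ka
#'
#' @param dG Gibbs free energy of binding, kJ/mol.
#' @param temperature absolute temperature, K.
#' @return Ka in L/mol such that \code{thermodynamics(Ka, ., temperature)}
#'   returns \code{dG} to machine precision.
#' @export
ka_from_energy <- function(dG, temperature = 300) {
  stopifnot(temperature > 0)
  exp(-dG * 1000 / (GAS_CONSTANT_SI * temperature))
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Binding thermodynamics at", x$temperature, "K\n")
  cat(sprintf("  Ka  = %.6g L/mol\n", x$Ka))
  cat(sprintf("  dH  = %8.3f kJ/mol\n", x$dH))
  cat(sprintf("  dG  = %8.3f kJ/mol\n", x$dG))
  cat(sprintf("  TdS = %8.3f kJ/mol   (TdS = dH - dG)\n", x$TdS))
  invisible(x)
}
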