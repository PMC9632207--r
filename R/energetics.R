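#' Energy unit conversion
#'
#' Exact interconversion between kJ/mol and kcal/mol using the
#' thermochemical factor 4.184 kJ/kcal.
#'
#' @param value numeric energy value(s).
#' @param from,to \code{"kJ/mol"} or \code{"kcal/mol"}.
#' @return converted value(s).
#' @export
convert_energy <- function(value, from, to) {
  units <- c("kJ/mol", "kcal/mol")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(value)
  if (from == "kcal/mol") value * KJ_PER_KCAL else value / KJ_PER_KCAL
}

#' Inhibition constant from a docking binding energy
#'
#' Docking convention: \code{Ki = exp(dG / (R*T))} with dG in kcal/mol,
#' R = 1.98722e-3 kcal mol^-1 K^-1 and T = 298.15 K by default (distinct
#' from the 300 K ITC convention; the two are never mixed silently).
#' A binding energy of 0 gives Ki = 1 mol/L.
#'
#' @param dG binding free energy, kcal/mol (negative for favourable
#'   binding).
#' @param temperature absolute temperature, K.
#' @return Ki in mol/L.
#' @seealso \code{\link{energy_from_ki}} for the exact inverse.
#' @export
ki_from_energy <- function(dG, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive")
  exp(dG / (GAS_CONSTANT_KCAL * temperature))
}

#' Docking binding energy from an inhibition constant
#'
#' @param ki inhibition constant, mol/L (> 0).
#' @param temperature absolute temperature, K.
#' @return dG in kcal/mol; exact inverse of \code{\link{ki_from_energy}}.
#' @export
energy_from_ki <- function(ki, temperature = 298.15) {
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(all(ki > 0))
  GAS_CONSTANT_KCAL * temperature * log(ki)
}

#' MM-PBSA energy components
#'
#' Container for a binding-enthalpy decomposition in kJ/mol: the
#' molecular-mechanics electrostatic and van der Waals contributions and
#' the polar and nonpolar (SASA) solvation terms, plus an optional
#' independently reported total for bookkeeping.
#'
#' @param electrostatic,vdw,polar_solvation,sasa component energies,
#'   kJ/mol.
#' @param reported_total optional externally reported total, kJ/mol.
#' @return object of class \code{"mmpbsa_components"}.
#' @export
mmpbsa_components <- function(electrostatic, vdw, polar_solvation, sasa,
                              reported_total = NULL) {
  vals <- c(electrostatic, vdw, polar_solvation, sasa)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("all four components (electrostatic, vdw, polar_solvation, sasa) ",
         "must be finite numbers")
  structure(list(electrostatic = electrostatic, vdw = vdw,
                 polar_solvation = polar_solvation, sasa = sasa,
                 reported_total = reported_total),
            class = "mmpbsa_components")
}

#' Sum MM-PBSA components and surface the bookkeeping residual
#'
#' \code{total = electrostatic + vdw + polar_solvation + sasa}. When an
#' independently reported total is present, the residual
#' \code{reported_total - total} is returned alongside and printed --
#' never silently absorbed. Entropic (-TdS) terms are not part of this
#' sum; the total is an enthalpy-level estimate.
#'
#' @param components an \code{mmpbsa_components} object.
#' @return list with \code{total} (kJ/mol) and
#'   \code{residual_vs_reported} (kJ/mol or NA when no reported total).
#' @export
sum_components <- function(components) {
  stopifnot(inherits(components, "mmpbsa_components"))
  total <- components$electrostatic + components$vdw +
    components$polar_solvation + components$sasa
  residual <- if (is.null(components$reported_total)) NA_real_
              else components$reported_total - total
  list(total = total, residual_vs_reported = residual)
}

#' @export
print.mmpbsa_components <- function(x, ...) {
  s <- sum_components(x)
  cat("MM-PBSA binding energy components (kJ/mol)\n")
  cat(sprintf("  electrostatic:   %10.3f\n", x$electrostatic))
  cat(sprintf("  van der Waals:   %10.3f\n", x$vdw))
  cat(sprintf("  polar solvation: %10.3f\n", x$polar_solvation))
  cat(sprintf("  SASA (nonpolar): %10.3f\n", x$sasa))
  cat(sprintf("  component sum:   %10.3f\n", s$total))
  if (!is.na(s$residual_vs_reported))
    cat(sprintf("  reported total:  %10.3f  (residual %+.3f kJ/mol)\n",
                x$reported_total, s$residual_vs_reported))
  invisible(x)
}

#' Compare binding free energies across methods
#'
#' Places ITC-derived, docking and MM-PBSA binding free energies on a
#' common kJ/mol scale and reports the values, all pairwise differences,
#' sign agreement and the ordering from most to least favourable. No
#' statistical claim is attached: the methods estimate related but not
#' identical quantities (the MM-PBSA total here omits the entropic
#' term).
#'
#' @param itc_dG ITC-derived dG, kJ/mol (or a \code{thermo_result}).
#' @param docking_dG docking binding energy, kcal/mol by convention;
#'   set \code{docking_unit} if already in kJ/mol.
#' @param mmpbsa_total MM-PBSA total, kJ/mol.
#' @param docking_unit unit of \code{docking_dG}.
#' @return object of class \code{"method_comparison"} with the kJ/mol
#'   values, pairwise difference matrix, and ordering.
#' @export
compare_methods <- function(itc_dG, docking_dG, mmpbsa_total,
                            docking_unit = "kcal/mol") {
  if (inherits(itc_dG, "thermo_result")) itc_dG <- itc_dG$dG
  docking_kJ <- convert_energy(docking_dG, docking_unit, "kJ/mol")
  vals <- c(ITC = itc_dG, docking = docking_kJ, MMPBSA = mmpbsa_total)
  diffs <- outer(vals, vals, `-`)
  out <- list(values_kJmol = vals,
              pairwise_differences = diffs,
              same_sign = length(unique(sign(vals))) == 1L,
              ordering = names(sort(vals)))
  class(out) <- "method_comparison"
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Binding free energy comparison (kJ/mol)\n")
  print(round(x$values_kJmol, 3))
  cat("pairwise differences (row - column):\n")
  print(round(x$pairwise_differences, 3))
  cat("all same sign:", x$same_sign, "\n")
  cat("most to least favourable:", paste(x$ordering, collapse = " < "), "\n")
  invisible(x)
}
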