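#' Titration experiment design
#'
#' Describes an ITC titration: ligand concentration in the syringe,
#' enzyme concentration in the cell, number and volume of injections,
#' cell volume, and temperature. The default mirrors a 30-injection
#' titration of an 8000 umol/L ligand stock into a 1.0 mL cell holding
#' 5 umol/L enzyme at 300 K.
#'
#' @param syringe_ligand_conc ligand stock concentration, umol/L.
#' @param cell_enzyme_conc enzyme concentration in the cell, umol/L.
#' @param n_injections number of injections (>= 2).
#' @param injection_volume volume per injection, uL.
#' @param cell_volume active cell volume, mL.
#' @param temperature absolute temperature, K.
#' @return object of class \code{"titration_design"}.
#' @export
titration_design <- function(syringe_ligand_conc = 8000,
                             cell_enzyme_conc = 5,
                             n_injections = 30,
                             injection_volume = 10,
                             cell_volume = 1,
                             temperature = 300) {
  stopifnot(syringe_ligand_conc > 0, cell_enzyme_conc > 0,
            n_injections >= 2, n_injections == round(n_injections),
            injection_volume > 0, cell_volume > 0, temperature > 0)
  if (injection_volume >= cell_volume * 1000)
    stop("injection volume must be smaller than the cell volume")
  structure(list(syringe_ligand_conc = syringe_ligand_conc,
                 cell_enzyme_conc = cell_enzyme_conc,
                 n_injections = as.integer(n_injections),
                 injection_volume = injection_volume,
                 cell_volume = cell_volume,
                 temperature = temperature),
            class = "titration_design")
}

#' Cumulative ligand concentration schedule
#'
#' Applies the standard perfusion approximation for an overflow cell:
#' each injection of volume v into active volume V displaces a fraction
#' v/V of the current contents, so after k injections the cumulative
#' ligand concentration is \code{C_syr * (1 - (1 - v/V)^k)} -- strictly
#' increasing and bounded above by the syringe concentration.
#'
#' @param design a \code{titration_design}.
#' @return numeric vector of length \code{n_injections}, umol/L.
#' @export
injection_schedule <- function(design) {
  stopifnot(inherits(design, "titration_design"))
  f <- design$injection_volume / (design$cell_volume * 1000)
  k <- seq_len(design$n_injections)
  conc <- design$syringe_ligand_conc * (1 - (1 - f)^k)
  if (any(conc <= 0)) stop("invalid design: nonpositive ligand concentration")
  conc
}

# internal constructor for the central titration container
new_titration_series <- function(df, design, truth = NULL, seed = NULL,
                                 heat_unit = "uJ") {
  stopifnot(all(c("injection", "ligand_uM", "heat") %in% names(df)))
  if (any(diff(df$ligand_uM) <= 0))
    stop("ligand concentrations must be strictly increasing")
  structure(df, class = c("titration_series", "data.frame"),
            design = design, truth = truth, seed = seed,
            heat_unit = heat_unit)
}

#' Simulate an ITC titration under the extended solvation model
#'
#' Forward-evaluates the solvation heat model on the injection schedule
#' of \code{design} and adds optional Gaussian noise. If a dilution-heat
#' polynomial is supplied, the relative partial molar enthalpies LA/LB
#' entering the model are computed analytically from it (the tangent
#' construction in closed form) and stored as columns of the series;
#' without one, LA = LB = 0 and the model reduces to
#' \code{q = q_max * xB'}.
#'
#' The ground-truth parameters and seed are attached as attributes so
#' recovery tests can compare estimates against them.
#'
#' @param design a \code{titration_design}.
#' @param truth a \code{solvation_parameters} object (the ground truth).
#' @param dilution_coef optional numeric vector of polynomial
#'   coefficients (increasing power) for the dilution heat q_dil(xB).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   heats (same units); 0 disables noise.
#' @param seed RNG seed; required when \code{noise_sd > 0}.
#' @return a \code{titration_series} with columns \code{injection},
#'   \code{ligand_uM}, \code{heat}, \code{LA}, \code{LB}.
#' @export
simulate_titration <- function(design, truth, dilution_coef = NULL,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(design, "titration_design"),
            inherits(truth, "solvation_parameters"), noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  conc <- injection_schedule(design)
  xB <- conc / max(conc)
  if (is.null(dilution_coef)) {
    LA <- rep(0, length(xB)); LB <- rep(0, length(xB))
  } else {
    qd <- polyval(dilution_coef, xB)
    dq <- polyval(polyderiv(dilution_coef), xB)
    LA <- qd - xB * dq
    LB <- qd + (1 - xB) * dq
  }
  q <- predict_heats(truth, xB, LA, LB)
  if (noise_sd > 0)
    q <- q + with_seed(seed, rnorm(length(q), sd = noise_sd))
  new_titration_series(
    data.frame(injection = seq_along(conc), ligand_uM = conc, heat = q,
               LA = LA, LB = LB),
    design = design, truth = truth, seed = seed)
}

#' Simulate a ligand dilution-heat series
#'
#' Evaluates a polynomial dilution-heat profile on a mole-fraction grid
#' and adds optional Gaussian noise.
#'
#' @param xB_grid strictly increasing grid in [0, 1].
#' @param coefficients polynomial coefficients, increasing power order.
#' @param noise_sd Gaussian noise sd; 0 disables.
#' @param seed RNG seed; required when \code{noise_sd > 0}.
#' @return a \code{dilution_series} data.frame with columns \code{xB},
#'   \code{q_dilut}; truth attributes attached.
#' @export
simulate_dilution <- function(xB_grid, coefficients, noise_sd = 0,
                              seed = NULL) {
  if (length(xB_grid) == 0L) stop("empty xB grid")
  stopifnot(all(xB_grid >= 0 & xB_grid <= 1), all(diff(xB_grid) > 0),
            noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  q <- polyval(coefficients, xB_grid)
  if (noise_sd > 0)
    q <- q + with_seed(seed, rnorm(length(q), sd = noise_sd))
  structure(data.frame(xB = xB_grid, q_dilut = q),
            class = c("dilution_series", "data.frame"),
            truth = list(coefficients = coefficients), seed = seed)
}

#' Kinetics experiment design
#'
#' @param substrate_grid strictly increasing substrate concentrations, mM.
#' @param inhibitor_grid nonnegative inhibitor concentrations, uM;
#'   should start at 0 when mechanism classification is intended.
#' @param replicates replicate measurements per grid cell.
#' @return object of class \code{"kinetics_design"}.
#' @export
kinetics_design <- function(substrate_grid = c(1, 2, 4, 8, 16, 32),
                            inhibitor_grid = c(0, 0.5, 1, 2.5, 5),
                            replicates = 1) {
  stopifnot(length(substrate_grid) >= 3L, all(substrate_grid > 0),
            all(diff(substrate_grid) > 0),
            all(inhibitor_grid >= 0), replicates >= 1)
  structure(list(substrate_grid = substrate_grid,
                 inhibitor_grid = inhibitor_grid,
                 replicates = as.integer(replicates)),
            class = "kinetics_design")
}

#' Simulate a steady-state inhibition rate grid
#'
#' Generates velocities from the chosen reversible-inhibition rate law
#' on the full substrate-by-inhibitor grid, with optional Gaussian noise,
#' and stores the ground truth for recovery tests.
#'
#' @param design a \code{kinetics_design}.
#' @param mechanism one of \code{"none"}, \code{"competitive"},
#'   \code{"noncompetitive"}, \code{"uncompetitive"}, \code{"mixed"}.
#' @param Vmax maximal velocity (rate units).
#' @param Km Michaelis constant, mM.
#' @param Ki inhibition constant, uM (ignored for \code{"none"}).
#' @param alpha mixed-mechanism factor (alpha = 1 is pure noncompetitive).
#' @param noise_sd Gaussian noise sd on velocities; 0 disables.
#' @param seed RNG seed; required when \code{noise_sd > 0}.
#' @return a \code{kinetics_dataset} data.frame with columns
#'   \code{substrate_mM}, \code{inhibitor_uM}, \code{velocity},
#'   \code{replicate}.
#' @export
simulate_kinetics <- function(design, mechanism, Vmax, Km, Ki = Inf,
                              alpha = 1, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(design, "kinetics_design"), noise_sd >= 0)
  mechanism <- match.arg(mechanism,
                         c("none", "competitive", "noncompetitive",
                           "uncompetitive", "mixed"))
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  grid <- expand.grid(substrate_mM = design$substrate_grid,
                      inhibitor_uM = design$inhibitor_grid,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  v <- rate_law(mechanism, Vmax = Vmax, Km = Km,
                S = grid$substrate_mM, I = grid$inhibitor_uM,
                Ki = Ki, alpha = alpha)
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(v), sd = noise_sd))
  structure(data.frame(grid[c("substrate_mM", "inhibitor_uM")],
                       velocity = v, replicate = grid$replicate),
            class = c("kinetics_dataset", "data.frame"),
            truth = list(mechanism = mechanism, Vmax = Vmax, Km = Km,
                         Ki = Ki, alpha = alpha),
            seed = seed)
}

#' Simulate a dose-response (fractional activity) curve
#'
#' Fractional enzyme activity under the two-parameter logistic in
#' log-concentration: \code{activity = 1 / (1 + (I/ic50)^slope)}, with
#' activity 1 at I = 0 and 0.5 at I = ic50.
#'
#' @param inhibitor_grid nonnegative inhibitor concentrations, uM; should
#'   span both sides of \code{ic50} for identifiability.
#' @param ic50 half-maximal inhibitory concentration, uM.
#' @param slope positive Hill-type slope of the logistic.
#' @param noise_sd Gaussian noise sd on activity; 0 disables.
#' @param seed RNG seed; required when \code{noise_sd > 0}.
#' @return a \code{dose_response} data.frame with columns
#'   \code{inhibitor_uM}, \code{activity}.
#' @export
simulate_dose_response <- function(inhibitor_grid, ic50, slope = 1,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(all(inhibitor_grid >= 0), ic50 > 0, slope > 0, noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  pos <- inhibitor_grid[inhibitor_grid > 0]
  if (length(pos) > 0 && (all(pos > ic50) || all(pos < ic50)))
    warning("inhibitor grid lies entirely on one side of ic50; ",
            "the IC50 may not be identifiable")
  act <- 1 / (1 + (inhibitor_grid / ic50)^slope)
  if (noise_sd > 0)
    act <- act + with_seed(seed, rnorm(length(act), sd = noise_sd))
  structure(data.frame(inhibitor_uM = inhibitor_grid, activity = act),
            class = c("dose_response", "data.frame"),
            truth = list(ic50 = ic50, slope = slope), seed = seed)
}

#' Simulate binding heats from the Hill equation
#'
#' Forward-evaluates \code{q = q_max * L^n / (Kd^n + L^n)} (L in mol/L,
#' Kd = 1/Ka) on a supplied ligand grid, with optional Gaussian noise.
#' Used to generate region-specific data with known Hill truth.
#'
#' @param ligand_uM strictly increasing ligand concentrations, umol/L.
#' @param n Hill coefficient (> 0).
#' @param Ka association constant, L/mol.
#' @param q_max saturation heat.
#' @param temperature K, stored with the series.
#' @param noise_sd Gaussian noise sd; 0 disables.
#' @param seed RNG seed; required when \code{noise_sd > 0}.
#' @return a \code{titration_series} with Hill ground truth attached.
#' @export
simulate_hill_series <- function(ligand_uM, n, Ka, q_max,
                                 temperature = 300, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(all(ligand_uM > 0), all(diff(ligand_uM) > 0), n > 0, Ka > 0,
            noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")
  L <- ligand_uM * 1e-6
  Kd <- 1 / Ka
  q <- q_max * L^n / (Kd^n + L^n)
  if (noise_sd > 0)
    q <- q + with_seed(seed, rnorm(length(q), sd = noise_sd))
  new_titration_series(
    data.frame(injection = seq_along(L), ligand_uM = ligand_uM, heat = q),
    design = list(temperature = temperature),
    truth = list(n = n, Ka = Ka, q_max = q_max), seed = seed)
}
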