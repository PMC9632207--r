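#' Physical constants used throughout
#'
#' Gas constant in SI units (J mol^-1 K^-1), gas constant in kcal units
#' (kcal mol^-1 K^-1, the docking convention), and the thermochemical
#' calorie conversion factor (kJ per kcal). These are fixed at build time
#' and never configurable at run time.
#'
#' @format Named numeric constants.
#' @name constants
NULL

#' @rdname constants
#' @export
GAS_CONSTANT_SI <- 8.314

#' @rdname constants
#' @export
GAS_CONSTANT_KCAL <- 1.98722e-3

#' @rdname constants
#' @export
KJ_PER_KCAL <- 4.184

# internal: evaluate a function under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# internal: polynomial evaluation, coefficients in increasing power order
polyval <- function(coefficients, x) {
  stopifnot(length(coefficients) >= 1L)
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefficients))) out <- out * x + coefficients[k]
  out
}

# internal: derivative coefficients of a polynomial (increasing power order)
polyderiv <- function(coefficients) {
  n <- length(coefficients)
  if (n <= 1L) return(0)
  coefficients[-1L] * seq_len(n - 1L)
}

#' @importFrom stats lm lm.fit optim nlminb optimize rnorm coef fitted
#'   residuals predict vcov median
#' @importFrom graphics plot lines abline legend grid
#' @importFrom utils read.csv write.csv
NULL
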