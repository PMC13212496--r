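#' Kinetic parameters of the three-compartment cytotoxicity model
#'
#' Bundles the nine kinetic parameters describing tumor growth, ratio-
#' dependent CAR-T cytolysis, cytolysis-driven effector proliferation, and
#' basal effector decay in the co-culture assay.
#'
#' @param kp1 Tumor proliferation rate (1/hour).
#' @param CT Assay tumor carrying capacity (cells).
#' @param kc Saturated CAR-T cytolytic rate (1/hour).
#' @param Kmr Cytolysis half-saturation in the CART/T ratio (unitless).
#'   Lower values shift the transition from low to high killing rates to
#'   lower effector-to-target ratios.
#' @param n Ratio exponent (cooperativity, unitless). Higher values give a
#'   steeper transition from low to high killing rates.
#' @param kp2 Tumor-driven CAR-T proliferation rate (1/hour).
#' @param Kmp Proliferation half-saturation constant (cells/hour); the
#'   cytolysis rate at which the proliferation response is half-maximal.
#' @param CE Assay effector carrying capacity (cells).
#' @param kd Basal CAR-T/T-cell death rate (1/hour).
#'
#' @return A named numeric vector of class `cart_params`.
#' @examples
#' p <- cart_params(kp1 = 0.045, CT = 4e5, kc = 0.10, Kmr = 2.5, n = 1.2,
#'                  kp2 = 0.05, Kmp = 500, CE = 2e6, kd = 0.01)
#' @export
cart_params <- function(kp1, CT, kc, Kmr, n, kp2, Kmp, CE, kd) {
  x <- c(kp1 = kp1, CT = CT, kc = kc, Kmr = Kmr, n = n,
         kp2 = kp2, Kmp = Kmp, CE = CE, kd = kd)
  validate_params(x)
  structure(x, class = "cart_params")
}

#' @export
print.cart_params <- function(x, ...) {
  cat("<cart_params>\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

param_names <- function() {
  c("kp1", "CT", "kc", "Kmr", "n", "kp2", "Kmp", "CE", "kd")
}

#' Names of the effector-associated parameters
#'
#' The parameters estimated from co-culture and effector-control assays
#' (as opposed to the tumor-control parameters `kp1` and `CT`).
#'
#' @return Character vector.
#' @export
effector_param_names <- function() {
  c("kc", "Kmr", "n", "kp2", "Kmp", "CE", "kd")
}

validate_params <- function(x) {
  nm <- param_names()
  if (!all(nm %in% names(x))) {
    stop("parameters must contain: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  x <- x[nm]
  if (any(!is.finite(x))) stop("all parameters must be finite", call. = FALSE)
  # scale constants must be strictly positive; rates and the exponent may
  # be zero (limiting cases used in controls and oracles)
  pos <- c("CT", "Kmr", "Kmp", "CE")
  if (any(x[pos] <= 0)) {
    stop("parameters ", paste(pos[x[pos] <= 0], collapse = ", "),
         " must be strictly positive", call. = FALSE)
  }
  nonneg <- c("kp1", "kc", "n", "kp2", "kd")
  if (any(x[nonneg] < 0)) {
    stop("parameters ", paste(nonneg[x[nonneg] < 0], collapse = ", "),
         " must be non-negative", call. = FALSE)
  }
  invisible(x)
}

as_cart_params <- function(x) {
  x <- unlist(x)[param_names()]
  validate_params(x)
  structure(x, class = "cart_params")
}

#' Reference parameter set
#'
#' A plausible parameter set for a moderately potent product in the default
#' assay (Raji-scale targets seeded at 4e4 cells, 72 h run). Used as the
#' center for sensitivity sweeps and as the default location of the
#' synthetic-cohort priors.
#'
#' @return A `cart_params` object.
#' @export
reference_params <- function() {
  cart_params(kp1 = 0.045, CT = 4e5, kc = 0.10, Kmr = 2.5, n = 1.2,
              kp2 = 0.05, Kmp = 500, CE = 2e6, kd = 0.01)
}

#' Box bounds for parameter estimation
#'
#' Lower and upper limits used both to draw multi-start initial guesses and
#' to constrain the local optimizer. Defaults span the biologically
#' plausible magnitudes implied by the assay scale (4e4-cell target seed,
#' 96-well carrying capacities, 72 h horizon) and a cooperativity range
#' bracketing `n` in [0.5, 2].
#'
#' @param lower,upper Named numeric vectors overriding individual defaults.
#' @return List of class `cart_bounds` with `lower` and `upper` named
#'   vectors over all nine parameters.
#' @export
param_bounds <- function(lower = NULL, upper = NULL) {
  lo <- c(kp1 = 1e-3, CT = 1e5, kc = 1e-3, Kmr = 1e-2, n = 0.1,
          kp2 = 1e-3, Kmp = 1, CE = 1e4, kd = 1e-5)
  hi <- c(kp1 = 0.2, CT = 1e7, kc = 1, Kmr = 1e2, n = 5,
          kp2 = 1, Kmp = 1e5, CE = 1e7, kd = 0.1)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(!is.finite(lo)) || any(!is.finite(hi))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lo <= 0)) stop("lower bounds must be positive", call. = FALSE)
  if (any(lo >= hi)) stop("lower bounds must be below upper bounds", call. = FALSE)
  structure(list(lower = lo, upper = hi), class = "cart_bounds")
}
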