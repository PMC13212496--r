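#' @useDynLib cartkin
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

new_state <- function(T, CART, TC) {
  x <- c(T = T, CART = CART, TC = TC)
  if (any(!is.finite(x))) stop("state must be finite", call. = FALSE)
  if (any(x < 0)) stop("state components must be non-negative", call. = FALSE)
  x
}

check_state <- function(state) {
  if (!all(c("T", "CART", "TC") %in% names(state))) {
    stop("state must have components T, CART, TC", call. = FALSE)
  }
  new_state(state[["T"]], state[["CART"]], state[["TC"]])
}

hill_ratio_fraction <- function(r, Kmr, n) {
  # written as 1/(1 + (Kmr/r)^n) so large ratios saturate without overflow
  if (r <= 0) {
    if (n == 0) 0.5 else 0
  } else {
    1 / (1 + (Kmr / r)^n)
  }
}

#' Ratio-dependent cytolysis rate
#'
#' The CAR-T-mediated tumor killing rate: a Hill function of the effector-
#' to-target ratio `CART/T`, saturating at `kc * T`, with half-
#' saturation ratio `Kmr` and cooperativity exponent `n`. At `T = 0` the
#' rate is 0 by continuity (no division is performed).
#'
#' @param params A [cart_params()] object.
#' @param state Named numeric state with components `T`, `CART`, `TC`
#'   (cells).
#' @return Killing rate in cells/hour, within `[0, kc * T]`.
#' @examples
#' p <- reference_params()
#' cytolysis_rate(p, c(T = 1e4, CART = 2e4, TC = 0))
#' @export
cytolysis_rate <- function(params, state) {
  params <- as_cart_params(params)
  state <- check_state(state)
  T <- state[["T"]]
  if (T == 0) return(0)
  r <- state[["CART"]] / T
  unname(params[["kc"]] * hill_ratio_fraction(r, params[["Kmr"]], params[["n"]]) * T)
}

#' Cytolysis-driven CAR-T proliferation rate
#'
#' Effector expansion responds to the tumor killing rate itself: a Hill
#' function (exponent 2) of the cytolysis rate `fc`, half-maximal at
#' `Kmp` cells/hour, saturating at `kp2 * cart`.
#'
#' @param params A [cart_params()] object.
#' @param fc Current cytolysis rate (cells/hour), non-negative.
#' @param cart Current CAR-T count (cells), non-negative.
#' @return Proliferation rate in cells/hour, within `[0, kp2 * cart]`.
#' @export
proliferation_rate <- function(params, fc, cart) {
  params <- as_cart_params(params)
  if (fc < 0 || cart < 0) stop("fc and cart must be non-negative", call. = FALSE)
  Kmp <- params[["Kmp"]]
  unname(params[["kp2"]] * fc^2 / (Kmp^2 + fc^2) * cart)
}

gompertz_term <- function(N, CE, invert = FALSE) {
  N <- max(N, 1)  # cap the singularity as N -> 0 at the one-cell floor
  if (invert) log(N / CE) else log(CE / N)
}

#' Time derivatives of the three-compartment model
#'
#' Right-hand side of the model: logistic tumor growth minus Hill-type
#' ratio-dependent cytolysis; CAR-T expansion driven by cytolysis and
#' restricted toward the effector carrying capacity by a Gompertz
#' crowding term `ln(CE / (TC + CART))` (capped at a one-cell floor);
#' first-order decay of both effector compartments.
#'
#' @param params A [cart_params()] object.
#' @param state Named numeric state `c(T=, CART=, TC=)` in cells.
#' @param legacy If `TRUE`, use the mass-action variant (killing and
#'   proliferation proportional to `CART * T`; `Kmr`, `n`, `Kmp`, `CE`
#'   unused), kept as a comparison baseline.
#' @param gompertz Orientation of the crowding term: `"standard"` is
#'   `ln(CE/N)` (positive below capacity); `"inverted"` is the opposite
#'   sign, exposed for sensitivity checks only.
#' @return Named numeric vector `c(T=, CART=, TC=)` of rates (cells/hour).
#' @examples
#' cart_derivatives(reference_params(), c(T = 1e5, CART = 2e4, TC = 6e4))
#' @export
cart_derivatives <- function(params, state, legacy = FALSE,
                             gompertz = c("standard", "inverted")) {
  params <- as_cart_params(params)
  state <- check_state(state)
  gompertz <- match.arg(gompertz)
  T <- state[["T"]]; CA <- state[["CART"]]; TC <- state[["TC"]]
  if (legacy) {
    fc <- params[["kc"]] * CA * T
    dCA <- params[["kp2"]] * CA * T - params[["kd"]] * CA
  } else {
    fc <- cytolysis_rate(params, state)
    fp <- proliferation_rate(params, fc, CA)
    g <- gompertz_term(CA + TC, params[["CE"]], invert = gompertz == "inverted")
    dCA <- fp * g - params[["kd"]] * CA
  }
  c(T = params[["kp1"]] * T * (1 - T / params[["CT"]]) - fc,
    CART = dCA,
    TC = -params[["kd"]] * TC)
}

#' @rdname cart_derivatives
#' @export
legacy_derivatives <- function(params, state) {
  cart_derivatives(params, state, legacy = TRUE)
}

parms_vector <- function(params, legacy = FALSE, invert = FALSE) {
  c(unclass(params)[param_names()], as.numeric(invert), as.numeric(legacy))
}

rhs_r <- function(params, legacy, gompertz) {
  function(t, y, parms) {
    nsys <- length(y) / 3
    dy <- numeric(length(y))
    for (i in seq_len(nsys)) {
      idx <- (3 * i - 2):(3 * i)
      s <- pmax(y[idx], 0)
      names(s) <- c("T", "CART", "TC")
      dy[idx] <- cart_derivatives(params, s, legacy = legacy,
                                  gompertz = gompertz)
    }
    list(dy)
  }
}

# Integrate one or more stacked (T, CART, TC) systems sharing a parameter
# set over `times`. `y0` is a numeric vector of length 3 * nsys. Returns a
# matrix with 3 * nsys state columns (time column dropped).
integrate_states <- function(params, y0, times, engine = "compiled",
                             legacy = FALSE, gompertz = "standard",
                             rtol = 1e-8, atol = 1e-6) {
  if (length(times) == 1L) {
    return(matrix(y0, nrow = 1))
  }
  if (engine == "compiled") {
    out <- deSolve::ode(y = y0, times = times, func = "cartkin_derivs",
                        parms = parms_vector(params, legacy,
                                             gompertz == "inverted"),
                        dllname = "cartkin", initfunc = "cartkin_init",
                        rtol = rtol, atol = atol, method = "lsoda")
  } else {
    out <- deSolve::ode(y = y0, times = times,
                        func = rhs_r(params, legacy, gompertz),
                        parms = NULL, rtol = rtol, atol = atol,
                        method = "lsoda")
  }
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out))) {
    stop("ODE integration failed (params: ",
         paste(sprintf("%s=%.4g", param_names(), unclass(params)),
               collapse = ", "), ")", call. = FALSE)
  }
  unname(out[, -1, drop = FALSE])
}

#' Simulate the two-phase cytotoxicity assay
#'
#' Phase 1 integrates targets alone from `(target_seed, 0, 0)` until
#' effector addition; at that instant the effector pool
#' `E = et_ratio * target_seed` (or `effectors`, if given) is split into
#' `CART = TE * E` and `TC = (1 - TE) * E` and phase 2 integrates the full
#' model to the end of the assay. Integration restarts at the jump, and
#' output is sampled on the protocol's reading grid (the effector-addition
#' timepoint carries the post-addition state).
#'
#' @param params A [cart_params()] object.
#' @param protocol An [assay_protocol()]. A target-only control is obtained
#'   with `et_ratio = 0`; an effector-only control by setting the
#'   protocol's `target_seed = 0` and passing `effectors`.
#' @param et_ratio Effector:target ratio (0 for a target control).
#' @param effectors Optional absolute effector count overriding
#'   `et_ratio * target_seed` (needed when `target_seed = 0`).
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`.
#' @param legacy,gompertz Passed to the model right-hand side; see
#'   [cart_derivatives()].
#' @param rtol,atol Solver tolerances (relative; absolute in cells).
#' @return A tibble of class `cart_sim` with columns `time_h`, `T`,
#'   `CART`, `TC`, carrying the protocol, parameters and ratio as
#'   attributes.
#' @examples
#' sim <- simulate_assay(reference_params(), assay_protocol(), et_ratio = 25)
#' nrow(sim)  # 289
#' @export
simulate_assay <- function(params, protocol, et_ratio, effectors = NULL,
                           engine = c("compiled", "R"), legacy = FALSE,
                           gompertz = c("standard", "inverted"),
                           rtol = 1e-8, atol = 1e-6) {
  params <- as_cart_params(params)
  engine <- match.arg(engine)
  gompertz <- match.arg(gompertz)
  stopifnot(inherits(protocol, "assay_protocol"), et_ratio >= 0)
  dt <- protocol$sampling_interval
  t_add <- protocol$effector_addition_time
  te <- protocol$transduction_efficiency
  E <- if (is.null(effectors)) et_ratio * protocol$target_seed else effectors

  t1 <- seq(0, t_add, by = dt)
  y0 <- c(protocol$target_seed, 0, 0)
  ph1 <- if (protocol$target_seed > 0) {
    integrate_states(params, y0, t1, engine, legacy, gompertz, rtol, atol)
  } else {
    matrix(rep(y0, each = length(t1)), ncol = 3)
  }

  y_add <- pmax(ph1[nrow(ph1), ], 0) + c(0, te * E, (1 - te) * E)
  t2 <- seq(t_add, protocol$total_duration, by = dt)
  ph2 <- integrate_states(params, y_add, t2, engine, legacy, gompertz,
                          rtol, atol)

  keep <- t1 < t_add
  out <- tibble::tibble(
    time_h = c(t1[keep], t2),
    T = c(ph1[keep, 1], ph2[, 1]),
    CART = c(ph1[keep, 2], ph2[, 2]),
    TC = c(ph1[keep, 3], ph2[, 3])
  )
  structure(out, class = c("cart_sim", class(out)),
            protocol = protocol, params = params, et_ratio = et_ratio)
}

#' Percent cytolysis relative to the target control
#'
#' `100 * (1 - T_coculture(t) / T_control(t))`, clipped to `[0, 100]`.
#' The reference is the simulated target-control trajectory at the same
#' timepoint (not the initial seed), since control tumors keep growing
#' over the assay.
#'
#' @param coculture,control `cart_sim` objects sharing the same protocol
#'   grid; `control` must be a target-only simulation.
#' @param t Timepoint(s) in hours, on the sampling grid.
#' @return Percent cytolysis, a numeric vector along `t`.
#' @export
percent_cytolysis <- function(coculture, control, t) {
  i <- match(round(t, 9), round(coculture$time_h, 9))
  j <- match(round(t, 9), round(control$time_h, 9))
  if (any(is.na(i)) || any(is.na(j))) {
    stop("t must lie on the shared sampling grid", call. = FALSE)
  }
  Tc <- control$T[j]
  if (any(Tc == 0)) stop("target-control population is zero at t", call. = FALSE)
  pmin(pmax(100 * (1 - coculture$T[i] / Tc), 0), 100)
}

#' Closed-form logistic growth
#'
#' Solution of `dT/dt = kp1 * T * (1 - T/CT)` from `T0`; the tumor-only
#' limit of the model, used for stage-1 fitting and as an integration
#' oracle.
#'
#' @param t Times in hours.
#' @param kp1 Growth rate (1/hour).
#' @param CT Carrying capacity (cells).
#' @param T0 Initial population (cells).
#' @return Population at `t` (cells).
#' @export
logistic_solution <- function(t, kp1, CT, T0) {
  CT / (1 + ((CT - T0) / T0) * exp(-kp1 * t))
}
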