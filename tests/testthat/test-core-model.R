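test_that("cytolysis rate obeys Hill identities and hand-computed values", {
  p <- ref_with(kc = 0.1, Kmr = 1, n = 2)
  # no CAR-T cells: no killing
  expect_equal(cytolysis_rate(p, c(T = 5e4, CART = 0, TC = 0)), 0)
  # ratio at half-saturation: exactly kc * T / 2
  p2 <- ref_with(kc = 0.2, Kmr = 0.5, n = 1.7)
  T <- 8e4
  expect_equal(cytolysis_rate(p2, c(T = T, CART = 0.5 * T, TC = 0)),
               0.2 * T / 2)
  # hand-evaluated: kc (r^n/(Kmr^n + r^n)) T = 0.1 * (4/5) * 1e4
  expect_equal(cytolysis_rate(p, c(T = 1e4, CART = 2e4, TC = 0)), 800)
  # empty well: zero by continuity, no division
  expect_equal(cytolysis_rate(p, c(T = 0, CART = 1e4, TC = 0)), 0)
  # bounded by kc * T on random states
  set.seed(11)
  for (i in 1:50) {
    st <- c(T = runif(1, 1, 1e6), CART = runif(1, 0, 1e6), TC = 0)
    expect_lte(cytolysis_rate(p2, st), 0.2 * st[["T"]] + 1e-9)
  }
  expect_error(cytolysis_rate(p, c(T = -1, CART = 0, TC = 0)),
               "non-negative")
})

test_that("proliferation rate obeys half-saturation and bounds", {
  p <- ref_with(kp2 = 0.05, Kmp = 100)
  expect_equal(proliferation_rate(p, 0, 1e4), 0)
  expect_equal(proliferation_rate(p, 100, 1e4), 0.05 * 1e4 / 2)
  # hand-evaluated: 0.05 * (9e4 / 1e5) * 1e4
  expect_equal(proliferation_rate(p, 300, 1e4), 450)
  set.seed(12)
  for (fc in runif(20, 0, 1e5)) {
    expect_lte(proliferation_rate(p, fc, 5e4), 0.05 * 5e4)
  }
  expect_error(proliferation_rate(p, -1, 10), "non-negative")
})

test_that("model derivatives match an independently coded right-hand side", {
  # independent one-liner evaluation of the analytic rates
  oracle <- function(p, s) {
    r <- if (s[1] > 0) s[2] / s[1] else 0
    fc <- if (s[1] > 0 && s[2] > 0) {
      p[["kc"]] * (r^p[["n"]] / (p[["Kmr"]]^p[["n"]] + r^p[["n"]])) * s[1]
    } else 0
    fp <- p[["kp2"]] * fc^2 / (p[["Kmp"]]^2 + fc^2) * s[2]
    g <- log(p[["CE"]] / max(s[2] + s[3], 1))
    c(p[["kp1"]] * s[1] * (1 - s[1] / p[["CT"]]) - fc,
      fp * g - p[["kd"]] * s[2],
      -p[["kd"]] * s[3])
  }
  set.seed(42)
  for (i in 1:100) {
    p <- ref_with(kc = runif(1, 0.01, 0.5), Kmr = runif(1, 0.1, 10),
                  n = runif(1, 0.2, 3), kp2 = runif(1, 0.01, 0.3),
                  Kmp = runif(1, 10, 5e3))
    s <- c(T = runif(1, 0, 5e5), CART = runif(1, 0, 5e5),
           TC = runif(1, 0, 5e5))
    got <- cart_derivatives(p, s)
    want <- oracle(unclass(p), unname(s))
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("derivatives handle fixed points and degenerate states", {
  p <- reference_params()
  expect_equal(unname(cart_derivatives(p, c(T = 0, CART = 0, TC = 0))),
               c(0, 0, 0))
  # logistic fixed point at carrying capacity
  d <- cart_derivatives(p, c(T = unclass(p)[["CT"]], CART = 0, TC = 0))
  expect_equal(d[["T"]], 0)
  # pure decay of untransduced cells
  p2 <- ref_with(kd = 0.01)
  d2 <- cart_derivatives(p2, c(T = 0, CART = 0, TC = 1e5))
  expect_equal(d2[["TC"]], -1000)
  # Gompertz cap: no NaN/Inf at empty effector pool
  d3 <- cart_derivatives(p, c(T = 1e4, CART = 0, TC = 0))
  expect_true(all(is.finite(d3)))
})

test_that("legacy mass-action variant uses bilinear rates", {
  p <- ref_with(kc = 1e-6, kp2 = 2e-6, kp1 = 0.04, CT = 1e6, kd = 0.01)
  expect_equal(unname(legacy_derivatives(p, c(T = 0, CART = 0, TC = 0))),
               c(0, 0, 0))
  s <- c(T = 1e4, CART = 1e4, TC = 0)
  d <- legacy_derivatives(p, s)
  fc <- 1e-6 * 1e4 * 1e4  # = 100 cells/hour
  expect_equal(d[["T"]], 0.04 * 1e4 * (1 - 1e4 / 1e6) - fc)
  expect_equal(d[["CART"]], 2e-6 * 1e4 * 1e4 - 0.01 * 1e4)
  # no tumor: only decay drives the effectors
  d0 <- legacy_derivatives(p, c(T = 0, CART = 5e3, TC = 0))
  expect_equal(d0[["CART"]], -0.01 * 5e3)
})

test_that("two-phase simulation matches closed forms and the protocol grid", {
  pr <- assay_protocol()
  p <- ref_with(kc = 0, kp2 = 0, kp1 = 0.045, CT = 4e5)
  ctrl <- simulate_assay(p, pr, et_ratio = 0)
  expect_equal(nrow(ctrl), 289)
  expect_true(!is.unsorted(ctrl$time_h, strictly = TRUE))
  # tumor-only limit follows the logistic solution everywhere
  want <- logistic_solution(ctrl$time_h, 0.045, 4e5, 4e4)
  expect_equal(ctrl$T, want, tolerance = 1e-6)
  # with kc = 0 the co-culture tumor equals the target control
  cc <- simulate_assay(p, pr, et_ratio = 25)
  expect_equal(cc$T, ctrl$T, tolerance = 1e-8)
  # full transduction sends the whole pool into the CART compartment
  pr1 <- assay_protocol(transduction_efficiency = 1)
  s1 <- simulate_assay(reference_params(), pr1, et_ratio = 1)
  i <- match(24, s1$time_h)
  expect_equal(s1$CART[i], 4e4)
  expect_equal(s1$TC[i], 0)
})

test_that("effector-only wells decay exponentially from addition", {
  pr <- assay_protocol(target_seed = 0)
  p <- ref_with(kd = 0.013)
  sim <- simulate_assay(p, pr, et_ratio = 0, effectors = 2e5)
  post <- sim[sim$time_h >= 24, ]
  dtt <- post$time_h - 24
  expect_equal(post$CART, 0.25 * 2e5 * exp(-0.013 * dtt), tolerance = 1e-6)
  expect_equal(post$TC, 0.75 * 2e5 * exp(-0.013 * dtt), tolerance = 1e-6)
  expect_true(all(sim$T == 0))
})

test_that("compiled and R engines agree and states stay non-negative", {
  pr <- fast_protocol()
  set.seed(7)
  for (i in 1:4) {
    p <- ref_with(kc = runif(1, 0.02, 0.4), Kmr = runif(1, 0.2, 8),
                  n = runif(1, 0.3, 2.5), kd = runif(1, 1e-3, 0.05))
    sc <- simulate_assay(p, pr, et_ratio = 6.25)
    sr <- simulate_assay(p, pr, et_ratio = 6.25, engine = "R")
    expect_equal(sc$T, sr$T, tolerance = 1e-6)
    expect_equal(sc$CART, sr$CART, tolerance = 1e-6)
    expect_true(min(sc$T, sc$CART, sc$TC) >= -1e-6)
  }
  # inverted crowding orientation is exposed and runs
  si <- simulate_assay(reference_params(), pr, et_ratio = 1,
                       gompertz = "inverted")
  expect_true(all(is.finite(si$CART)))
})

test_that("percent cytolysis is a clipped relative tumor reduction", {
  pr <- fast_protocol()
  p <- reference_params()
  ctrl <- simulate_assay(p, pr, et_ratio = 0)
  expect_equal(percent_cytolysis(ctrl, ctrl, 48), 0)
  cc <- simulate_assay(p, pr, et_ratio = 25)
  # arithmetic: T_cc = 2e4 vs T_ctrl = 8e4 would give 75
  fake <- ctrl
  fake$T <- ctrl$T * 0.25
  expect_equal(percent_cytolysis(fake, ctrl, 48), 75)
  expect_true(all(percent_cytolysis(cc, ctrl, c(24, 48, 72)) >= 0))
  expect_error(percent_cytolysis(cc, ctrl, 47.9876), "grid")
})

test_that("final cytolysis responds monotonically to kc and Kmr", {
  pr <- fast_protocol()
  ctrl <- simulate_assay(reference_params(), pr, et_ratio = 0)
  cyto <- function(p) {
    percent_cytolysis(simulate_assay(p, pr, et_ratio = 6.25), ctrl, 72)
  }
  kc_grid <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  v1 <- vapply(kc_grid, function(k) cyto(ref_with(kc = k)), numeric(1))
  expect_true(all(diff(v1) >= -1e-8))
  kmr_grid <- c(0.25, 0.5, 1, 2, 4)
  v2 <- vapply(kmr_grid, function(k) cyto(ref_with(Kmr = k)), numeric(1))
  expect_true(all(diff(v2) <= 1e-8))
})
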