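test_that("collective normalization maps the pooled range onto [0, 4]", {
  cfg <- fast_config()
  prod <- suppressWarnings(emit_traces(draw_product(cfg, 1), cfg))
  norm <- normalize_product(prod)
  expect_equal(min(norm$traces$ci), 0)
  expect_equal(max(norm$traces$ci), 4)
  # worked value: pooled min 0.5, max 2.5 maps 1.5 onto 2.0
  tr <- tibble::tibble(product_id = "X", condition = "target_control",
                       et_ratio = NA_real_, replicate = 1L,
                       time_h = c(0, 1, 2), ci = c(0.5, 1.5, 2.5))
  expect_equal(normalize_product(tr)$ci, c(0, 2, 4))
  # idempotent on its own output
  expect_equal(normalize_product(normalize_product(tr))$ci,
               normalize_product(tr)$ci)
  # invariant to positive affine rescaling of the raw data
  tr2 <- dplyr::mutate(tr, ci = 3.7 * ci + 11)
  expect_equal(normalize_product(tr2)$ci, normalize_product(tr)$ci)
  # constant data cannot be normalized
  tr3 <- dplyr::mutate(tr, ci = 2)
  expect_error(normalize_product(tr3), "range is zero")
})

test_that("start shift anchors at 1 CI and preserves differences", {
  tr <- tibble::tibble(product_id = "X", condition = "target_control",
                       et_ratio = NA_real_, replicate = 1L,
                       time_h = c(0, 1, 2), ci = c(2.4, 2.9, 3.1))
  sh <- shift_to_start(tr, anchor_time = 0)
  expect_equal(sh$ci, c(1, 1.5, 1.7))
  expect_equal(diff(sh$ci), diff(tr$ci))
  # already anchored traces are unchanged
  expect_equal(shift_to_start(sh, 0)$ci, sh$ci)
  # a flat trace at 0 becomes a flat trace at 1
  tr0 <- dplyr::mutate(tr, ci = 0)
  expect_equal(shift_to_start(tr0, 0)$ci, rep(1, 3))
  expect_error(shift_to_start(tr, anchor_time = 0.5), "grid")
})

test_that("effector-addition time is declared or detected from the CI jump", {
  cfg <- fast_config()
  prod <- suppressWarnings(emit_traces(draw_product(cfg, 1), cfg))
  expect_equal(resolve_addition_time(prod, declared = 24), 24)
  # injected step at 24.25 h is found as the largest first difference
  times <- seq(0, 72, by = 0.25)
  ci <- 1 + 0.005 * times + ifelse(times >= 24.25, 0.8, 0)
  tr <- tibble::tibble(product_id = "X", condition = "coculture",
                       et_ratio = 1, replicate = 1L, time_h = times,
                       ci = ci)
  tc <- dplyr::mutate(tr, condition = "target_control", et_ratio = NA_real_,
                      ci = 1 + 0.005 * times)
  p <- cart_product(dplyr::bind_rows(tr, tc), te = 0.25)
  expect_equal(resolve_addition_time(p, declared = NULL), 24.25)
  # a smooth monotone trace has no detectable addition
  p2 <- cart_product(dplyr::bind_rows(dplyr::mutate(tr, ci = 1 + 0.005 * times),
                                      tc), te = 0.25)
  expect_error(resolve_addition_time(p2, declared = NULL), "no positive")
})

test_that("calibration slopes follow the known initial conditions", {
  prod <- linear_product(ts = 2.5e-5, se = 1.25e-5, base = 0,
                         growth_per_h = 0)
  pr <- assay_protocol()
  curve <- fit_calibration(prod, pr, baseline = 0)
  # CI(0) = 1.0 over a 4e4 seed
  expect_equal(curve$target_slope, 2.5e-5)
  # jump of 0.5 at rho = 1 corresponds to 1.25e-5 CI per effector cell
  expect_equal(curve$effector_slope, 1.25e-5)
  # tumor growth within the reading interval does not bias the slope
  prod2 <- linear_product(ts = 2.5e-5, se = 1.25e-5, growth_per_h = 0.02)
  curve2 <- fit_calibration(prod2, pr, baseline = 0)
  expect_equal(curve2$effector_slope, 1.25e-5, tolerance = 1e-10)
  # no jump at addition: polarity violated
  prod3 <- linear_product(se = 1e-30)
  prod3$traces$ci <- ifelse(prod3$traces$condition == "coculture",
                            1, prod3$traces$ci)
  expect_error(fit_calibration(prod3, pr, baseline = 0), "effector slope")
})

test_that("cell-index map is linear, additive and invertible", {
  curve <- calibration_curve(2.5e-5, 1.25e-5, baseline = 0)
  expect_equal(ci_from_cells(c(T = 0, CART = 0, TC = 0), curve), 0)
  expect_equal(ci_from_cells(c(T = 4e4, CART = 0, TC = 0), curve), 1.0)
  # effector contribution is independent of the tumor load
  d1 <- ci_from_cells(c(T = 1e5, CART = 2e4, TC = 1e4), curve) -
    ci_from_cells(c(T = 1e5, CART = 0, TC = 0), curve)
  d2 <- ci_from_cells(c(T = 3e5, CART = 2e4, TC = 1e4), curve) -
    ci_from_cells(c(T = 3e5, CART = 0, TC = 0), curve)
  expect_equal(d1, d2)
  # round trip for a single known population
  for (n_cells in c(1, 437, 4e4, 9.9e5)) {
    ci <- ci_from_cells(c(T = n_cells, CART = 0, TC = 0), curve)
    expect_equal(cells_from_ci(ci, curve, "target"), n_cells,
                 tolerance = 1e-12)
  }
  expect_error(calibration_curve(-1, 1), "positive")
})

test_that("the addition reading is imputed from the effector control", {
  times <- seq(0, 48, by = 0.25)
  cc <- tibble::tibble(product_id = "X", condition = "coculture",
                       et_ratio = 1, replicate = 1L, time_h = times,
                       ci = rep(1.2, length(times)))
  ec <- tibble::tibble(product_id = "X", condition = "effector_control",
                       et_ratio = NA_real_, replicate = 1L, time_h = times,
                       ci = ifelse(times >= 24, 0.3, 0))
  out <- impute_addition_ci(cc, ec, t_add = 24)
  i <- match(24, times)
  expect_equal(out$ci[i], 1.5)
  expect_equal(out$ci[-i], cc$ci[-i])
  # zero effector-control CI leaves the prior value
  ec0 <- dplyr::mutate(ec, ci = 0)
  expect_equal(impute_addition_ci(cc, ec0, 24)$ci[i], 1.2)
  expect_error(impute_addition_ci(cc, ec, t_add = 0), "precedes")
})

test_that("the cohort mean dataset averages aligned traces", {
  cfg <- fast_config(noise_cv = 0, noise_sd = 0)
  base <- draw_product(cfg, 1)
  p1 <- suppressWarnings(emit_traces(base, cfg))
  # identical products: the mean equals any member
  m <- build_mean_dataset(list(p1, p1), protocol = cfg$protocol)
  one_well <- dplyr::filter(p1$traces, condition == "coculture",
                            et_ratio == 25, replicate == 1)
  m_well <- dplyr::filter(m$traces, condition == "coculture",
                          et_ratio == 25)
  expect_equal(m_well$ci, one_well$ci, tolerance = 1e-9)
  expect_true(isTRUE(m$synthetic_mean))
  # constant traces at 1 and 3 average to 2
  times <- seq(0, 72, 0.5)
  mk <- function(id, v) {
    dplyr::bind_rows(
      tibble::tibble(product_id = id, condition = "target_control",
                     et_ratio = NA_real_, replicate = 1L, time_h = times,
                     ci = v),
      tibble::tibble(product_id = id, condition = "coculture",
                     et_ratio = 1, replicate = 1L, time_h = times,
                     ci = v + ifelse(times >= 24, 0.5, 0)))
  }
  pa <- cart_product(mk("A", 1), te = 0.3, addition_time = 24)
  pb <- cart_product(mk("B", 3), te = 0.3, addition_time = 24)
  mm <- build_mean_dataset(list(pa, pb),
                           protocol = fast_protocol())
  tc <- dplyr::filter(mm$traces, condition == "target_control")
  expect_true(all(abs(tc$ci - 2) < 1e-12))
  # mismatched ratio sets are rejected
  pc <- cart_product(dplyr::mutate(mk("C", 1),
                                   et_ratio = dplyr::if_else(is.na(et_ratio),
                                                             NA_real_, 2)),
                     te = 0.3, addition_time = 24)
  expect_error(build_mean_dataset(list(pa, pc), fast_protocol()),
               "inconsistent")
})

test_that("co-culture phases align on each product's own addition time", {
  times <- seq(0, 72, 0.25)
  mk <- function(id, t_add) {
    dplyr::bind_rows(
      tibble::tibble(product_id = id, condition = "target_control",
                     et_ratio = NA_real_, replicate = 1L, time_h = times,
                     ci = 1),
      tibble::tibble(product_id = id, condition = "coculture",
                     et_ratio = 1, replicate = 1L, time_h = times,
                     # post-addition decline indexed on the product's own clock
                     ci = ifelse(times >= t_add,
                                 2 - 0.01 * (times - t_add), 1)))
  }
  pa <- cart_product(mk("A", 24), te = 0.3, addition_time = 24)
  pb <- cart_product(mk("B", 24.25), te = 0.3, addition_time = 24.25)
  m <- build_mean_dataset(list(pa, pb), protocol = assay_protocol())
  cc <- dplyr::filter(m$traces, condition == "coculture",
                      time_h >= 24, time_h <= 47)
  # aligned averaging keeps the common post-addition shape exactly
  expect_equal(cc$ci, 2 - 0.01 * (cc$time_h - 24), tolerance = 1e-9)
})
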