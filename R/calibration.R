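#' Normalize a product's traces to a common 0-4 cell-index scale
#'
#' Raw impedance traces vary in starting value and magnitude between
#' assays, so all of a product's traces (controls and co-cultures pooled)
#' are mapped collectively by
#' `(CI - CI_min) / (CI_max - CI_min) * 4`, where the minimum and maximum
#' are taken over the product's pooled readings. After normalization the
#' pooled minimum is 0 and the pooled maximum is 4. The map is affine, so
#' it is idempotent and invariant to positive affine rescalings of the
#' raw data.
#'
#' @param traces Tidy trace tibble for one product (see
#'   [validate_traces()]), or a [cart_product()].
#' @return Object of the same type with normalized `ci`.
#' @export
normalize_product <- function(traces) {
  if (inherits(traces, "cart_product")) {
    traces$traces <- normalize_product(traces$traces)
    return(traces)
  }
  validate_traces(traces)
  lo <- min(traces$ci)
  hi <- max(traces$ci)
  if (hi - lo <= 0) {
    stop("cannot normalize: pooled cell-index range is zero", call. = FALSE)
  }
  dplyr::mutate(traces, ci = (.data$ci - lo) / (hi - lo) * 4)
}

#' Shift traces to a fixed starting cell index
#'
#' Additively shifts each well's trace so that its value at `anchor_time`
#' equals 1 CI, the conventional presentation anchor at target addition.
#' The shift preserves all within-trace differences exactly; it is used
#' for visualization and cross-product comparison, while estimation works
#' on the normalized (unshifted) scale.
#'
#' @param trace Tidy trace tibble (one or more wells).
#' @param anchor_time Time (hours) at which the shifted value is 1; must
#'   be on every well's grid.
#' @return Shifted traces.
#' @export
shift_to_start <- function(trace, anchor_time = 0) {
  validate_traces(trace)
  trace |>
    dplyr::group_by(.data$product_id, .data$condition, .data$et_ratio,
                    .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      i <- match(round(anchor_time, 9), round(d$time_h, 9))
      if (is.na(i)) {
        stop("anchor_time is not on the trace grid", call. = FALSE)
      }
      dplyr::mutate(d, ci = .data$ci + (1 - .data$ci[i]))
    }) |>
    dplyr::ungroup()
}

#' Resolve the effector-addition timepoint
#'
#' When the addition time is recorded (instrument log, or a synthetic
#' product's protocol) it is authoritative and passed through. Otherwise
#' the addition is located as the grid time of the largest single-step
#' positive cell-index jump across the product's co-culture traces within
#' `window` (suspension effectors produce an immediate CI step on
#' addition).
#'
#' @param dataset A [cart_product()] (needs at least one co-culture
#'   trace).
#' @param declared Declared addition time in hours, or `NULL` to detect.
#' @param window Hours within which to search for the jump.
#' @return Addition time in hours.
#' @export
resolve_addition_time <- function(dataset, declared = NULL,
                                  window = c(20, 28)) {
  if (!is.null(declared) && !is.na(declared)) return(declared)
  cc <- dplyr::filter(dataset$traces, .data$condition == "coculture")
  if (nrow(cc) == 0) stop("no coculture traces available", call. = FALSE)
  steps <- cc |>
    dplyr::group_by(.data$et_ratio, .data$replicate) |>
    dplyr::reframe(time_h = .data$time_h[-1], dci = diff(.data$ci))
  jumps <- dplyr::filter(steps, .data$time_h >= window[1],
                         .data$time_h <= window[2], .data$dci > 0)
  # an addition step must stand clear of ordinary growth/noise increments
  floor_d <- 5 * stats::median(abs(steps$dci)) + 1e-12
  if (nrow(jumps) == 0 || max(jumps$dci) <= floor_d) {
    stop("no positive cell-index jump found in the addition window",
         call. = FALSE)
  }
  jumps$time_h[which.max(jumps$dci)]
}

#' Linear cell-count / cell-index calibration
#'
#' Adherent targets and suspended effectors contribute to the measured
#' cell index with different (linear) weights; a calibration curve maps a
#' model state to CI as
#' `CI = baseline + target_slope * T + effector_slope * (CART + TC)`.
#' Dead cells contribute nothing (lysis removes impedance).
#'
#' @param target_slope,effector_slope CI per cell; strictly positive.
#' @param baseline CI of an empty well on the working scale.
#' @return List of class `calibration_curve`.
#' @export
calibration_curve <- function(target_slope, effector_slope, baseline = 0) {
  if (!is.finite(target_slope) || !is.finite(effector_slope) ||
      !is.finite(baseline)) {
    stop("calibration values must be finite", call. = FALSE)
  }
  if (target_slope <= 0 || effector_slope <= 0) {
    stop("calibration slopes must be positive (assay polarity violated)",
         call. = FALSE)
  }
  structure(list(target_slope = target_slope,
                 effector_slope = effector_slope, baseline = baseline),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n",
      sprintf("  target slope:   %.4g CI/cell\n", x$target_slope),
      sprintf("  effector slope: %.4g CI/cell\n", x$effector_slope),
      sprintf("  baseline:       %.4g CI\n", x$baseline), sep = "")
  invisible(x)
}

#' Fit a per-product calibration curve from known conditions
#'
#' Uses the known initial conditions of the assay. The baseline (empty-
#' well CI) is estimated from the pre-addition portion of the effector-
#' control wells, which contain only medium before the effectors arrive
#' (falling back to the pooled minimum, 0 on the normalized scale, when
#' no effector control is available). The target slope is the mean
#' target-control CI at time zero, minus baseline, divided by the target
#' seed. The effector slope regresses the CI step at effector addition on
#' the known effector count through the origin across all co-culture
#' wells; each step is corrected for the tumor-growth increment within
#' the reading interval using the preceding step of the same trace.
#'
#' @param dataset A [cart_product()] whose traces are on the working
#'   (normalized) scale.
#' @param protocol The [assay_protocol()] of the assay.
#' @param baseline Background CI on the working scale, or `"auto"`
#'   (default) to estimate it from pre-addition effector-control
#'   readings.
#' @param addition_time Effector-addition time; resolved from the dataset
#'   if `NULL`.
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(dataset, protocol, baseline = "auto",
                            addition_time = NULL) {
  tr <- dataset$traces
  t_add <- resolve_addition_time(dataset, declared = addition_time %||%
                                   dataset$addition_time)
  if (identical(baseline, "auto")) {
    ec_pre <- tr |>
      dplyr::filter(.data$condition == "effector_control",
                    .data$time_h < t_add - 1e-9)
    baseline <- if (nrow(ec_pre) > 0) mean(ec_pre$ci) else 0
  }
  tc0 <- tr |>
    dplyr::filter(.data$condition == "target_control",
                  abs(.data$time_h) < 1e-9)
  if (nrow(tc0) == 0) stop("no target-control reading at time zero",
                           call. = FALSE)
  target_slope <- (mean(tc0$ci) - baseline) / protocol$target_seed

  dt <- protocol$sampling_interval
  jumps <- tr |>
    dplyr::filter(.data$condition == "coculture") |>
    dplyr::group_by(.data$et_ratio, .data$replicate) |>
    dplyr::summarise(
      jump = ci_step(.data$ci, .data$time_h, t_add, dt),
      .groups = "drop")
  if (any(is.na(jumps$jump))) {
    stop("addition timepoint (or its predecessors) missing from a coculture trace",
         call. = FALSE)
  }
  effectors <- jumps$et_ratio * protocol$target_seed
  effector_slope <- sum(jumps$jump * effectors) / sum(effectors^2)
  if (!is.finite(effector_slope) || effector_slope <= 0) {
    stop("non-positive effector slope: no cell-index step at addition",
         call. = FALSE)
  }
  calibration_curve(target_slope, effector_slope, baseline)
}

# CI step at effector addition, corrected for within-interval tumor
# growth by subtracting the preceding step of the same trace.
ci_step <- function(ci, time_h, t_add, dt) {
  i2 <- match(round(t_add, 9), round(time_h, 9))
  i1 <- match(round(t_add - dt, 9), round(time_h, 9))
  i0 <- match(round(t_add - 2 * dt, 9), round(time_h, 9))
  if (any(is.na(c(i0, i1, i2)))) return(NA_real_)
  (ci[i2] - ci[i1]) - (ci[i1] - ci[i0])
}

#' Map a model state (or simulation) to cell-index units
#'
#' @param state Named state vector `c(T=, CART=, TC=)`, or a `cart_sim`
#'   tibble.
#' @param curve A [calibration_curve()].
#' @return CI value(s).
#' @export
ci_from_cells <- function(state, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.data.frame(state)) {
    return(curve$baseline + curve$target_slope * state$T +
             curve$effector_slope * (state$CART + state$TC))
  }
  state <- check_state(state)
  curve$baseline + curve$target_slope * state[["T"]] +
    curve$effector_slope * (state[["CART"]] + state[["TC"]])
}

#' Invert the calibration for a single known population
#'
#' @param ci CI value(s).
#' @param curve A [calibration_curve()].
#' @param population Which single population the CI is attributed to.
#' @return Cell count(s).
#' @export
cells_from_ci <- function(ci, curve, population = c("target", "effector")) {
  population <- match.arg(population)
  slope <- switch(population, target = curve$target_slope,
                  effector = curve$effector_slope)
  (ci - curve$baseline) / slope
}

#' Impute the cell index at the effector-addition timepoint
#'
#' Plate handling at effector addition loses the reading at the addition
#' timepoint, so it is reconstructed as the co-culture CI at the prior
#' timepoint plus the corresponding effector-control CI at addition.
#'
#' @param coculture,effector_control Single-well tidy traces on the same
#'   grid.
#' @param t_add Addition time (hours); must be on the grid with a
#'   preceding point.
#' @return The co-culture trace with the addition reading replaced.
#' @export
impute_addition_ci <- function(coculture, effector_control, t_add) {
  if (!isTRUE(all.equal(coculture$time_h, effector_control$time_h))) {
    stop("traces must share the same time grid", call. = FALSE)
  }
  i <- match(round(t_add, 9), round(coculture$time_h, 9))
  if (is.na(i)) stop("t_add is not on the trace grid", call. = FALSE)
  if (i == 1) stop("no timepoint precedes the addition time", call. = FALSE)
  coculture$ci[i] <- coculture$ci[i - 1] + effector_control$ci[i]
  coculture
}

#' Average a cohort into a mean experimental dataset
#'
#' Builds the cohort-mean product: the target-control phase is averaged on
#' absolute time from target addition, while each product's co-culture and
#' effector-control traces are first aligned at that product's own
#' effector-addition time and then averaged pointwise on addition-relative
#' time. The result is re-timed to the nominal protocol grid and flagged
#' as a synthetic mean.
#'
#' @param cohort List of [cart_product()] objects with complete
#'   conditions; all must share the same set of E:T ratios.
#' @param protocol Nominal [assay_protocol()] defining the output grid.
#' @return A [cart_product()] with `product_id = "mean"`.
#' @export
build_mean_dataset <- function(cohort, protocol = assay_protocol()) {
  if (length(cohort) < 2) stop("need at least two products", call. = FALSE)
  ratios <- lapply(cohort, function(p) {
    sort(unique(stats::na.omit(p$traces$et_ratio)))
  })
  if (!all(vapply(ratios, function(r) isTRUE(all.equal(r, ratios[[1]])),
                  logical(1)))) {
    stop("products have inconsistent E:T ratios", call. = FALSE)
  }
  t_add_nom <- protocol$effector_addition_time
  dt <- protocol$sampling_interval

  aligned <- purrr::map_dfr(cohort, function(p) {
    t_add <- resolve_addition_time(p, declared = p$addition_time)
    p$traces |>
      dplyr::mutate(
        rel_h = dplyr::if_else(.data$condition == "target_control",
                               .data$time_h, .data$time_h - t_add))
  })
  mean_tr <- aligned |>
    dplyr::mutate(rel_h = round(.data$rel_h / dt) * dt) |>
    dplyr::group_by(.data$condition, .data$et_ratio, .data$rel_h) |>
    dplyr::summarise(ci = mean(.data$ci), .groups = "drop") |>
    dplyr::mutate(
      time_h = dplyr::if_else(.data$condition == "target_control",
                              .data$rel_h, .data$rel_h + t_add_nom),
      product_id = "mean", replicate = 1L) |>
    dplyr::filter(.data$time_h >= 0,
                  .data$time_h <= protocol$total_duration) |>
    dplyr::select("product_id", "condition", "et_ratio", "replicate",
                  "time_h", "ci") |>
    dplyr::arrange(.data$condition, .data$et_ratio, .data$time_h)

  out <- cart_product(mean_tr,
                      te = mean(vapply(cohort, `[[`, numeric(1), "te")),
                      effector_seed = mean(vapply(cohort, `[[`, numeric(1),
                                                  "effector_seed")),
                      addition_time = t_add_nom, product_id = "mean")
  out$synthetic_mean <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
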