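#' Configuration for the staged fitting pipeline
#'
#' @param n_starts Multi-start count for the co-culture stage (1000 by
#'   default, matching the estimation protocol; reduce for quick runs).
#' @param seed RNG seed driving all start draws.
#' @param bounds A [param_bounds()] object.
#' @param baseline Background CI on the working scale, or `"auto"` (see
#'   [fit_calibration()]).
#' @param protocol Nominal [assay_protocol()]; transduction efficiency and
#'   E:T ratios are overridden per product from its data.
#' @param maxiter Levenberg-Marquardt iteration cap per start (the best
#'   start is afterwards polished with a generous cap).
#' @param engine ODE engine, `"compiled"` or `"R"`.
#' @param include_controls Include target- and effector-control residuals
#'   in the stage-3 objective (off by default: stages 1-2 own the
#'   controls).
#' @return List of class `cart_fit_config`.
#' @export
fit_config <- function(n_starts = 1000, seed = 1, bounds = param_bounds(),
                       baseline = "auto", protocol = assay_protocol(),
                       maxiter = 100, engine = "compiled",
                       include_controls = FALSE) {
  structure(list(n_starts = n_starts, seed = seed, bounds = bounds,
                 baseline = baseline, protocol = protocol,
                 maxiter = maxiter, engine = engine,
                 include_controls = include_controls),
            class = "cart_fit_config")
}

# x, lo, hi on the log-parameter scale: absolute closeness test
at_bound <- function(x, lo, hi, tol = 1e-3) {
  (x - lo) <= tol | (hi - x) <= tol
}

#' Stage 1: tumor growth from target controls
#'
#' Least-squares fit of the closed-form logistic solution, mapped to CI
#' units through the calibration curve, to the full target-control
#' trace(s). Optimized over `log(kp1), log(CT)` from a small deterministic
#' start grid.
#'
#' @param target_controls Tidy traces of `target_control` wells on the
#'   working scale.
#' @param curve A [calibration_curve()].
#' @param bounds A [param_bounds()].
#' @param protocol The [assay_protocol()] (provides the target seed).
#' @return List with `kp1`, `CT`, `ssr`, and `degenerate` (`TRUE` when an
#'   estimate sits on a bound, e.g. for a growth-free trace).
#' @export
fit_tumor_growth <- function(target_controls, curve, bounds = param_bounds(),
                             protocol = assay_protocol()) {
  stopifnot(nrow(target_controls) > 0)
  tt <- target_controls$time_h
  obs <- target_controls$ci
  T0 <- protocol$target_seed
  lo <- log(bounds$lower[c("kp1", "CT")])
  hi <- log(bounds$upper[c("kp1", "CT")])
  fn <- function(th) {
    obs - (curve$baseline +
             curve$target_slope * logistic_solution(tt, exp(th[1]), exp(th[2]), T0))
  }
  starts <- as.matrix(expand.grid(
    kp1 = lo[1] + c(0.25, 0.5, 0.75) * (hi[1] - lo[1]),
    CT = lo[2] + c(0.25, 0.5, 0.75) * (hi[2] - lo[2])
  ))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(starts[i, ], lower = lo, upper = hi, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-10, ptol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
  }
  if (is.null(best)) stop("stage 1: logistic fit failed on all starts",
                          call. = FALSE)
  est <- exp(best$par)
  list(kp1 = unname(est[1]), CT = unname(est[2]), ssr = best$deviance,
       degenerate = any(at_bound(best$par, lo, hi)))
}

#' Stage 2: effector decay from effector controls
#'
#' Fits `baseline + A * exp(-kd * (t - t_add))` to the post-addition
#' portion of the effector-control trace(s); the amplitude `A` is fit
#' jointly so the decay rate does not depend on the effector-slope
#' estimate. A log-linear regression on background-subtracted CI provides
#' the starting values.
#'
#' @param effector_controls Tidy traces of `effector_control` wells.
#' @param curve A [calibration_curve()].
#' @param bounds A [param_bounds()].
#' @param t_add Effector-addition time (hours).
#' @return List with `kd`, `amplitude`, `ssr`, and `degenerate` (`TRUE`
#'   when `kd` sits on the lower bound, e.g. for a flat or rising trace).
#' @export
fit_effector_decay <- function(effector_controls, curve,
                               bounds = param_bounds(), t_add = 24) {
  d <- dplyr::filter(effector_controls, .data$time_h >= t_add - 1e-9)
  stopifnot(nrow(d) > 2)
  dt <- d$time_h - t_add
  obs <- d$ci
  y <- pmax(obs - curve$baseline, 1e-8)
  ll <- stats::lm.fit(cbind(1, dt), log(y))
  kd0 <- min(max(-ll$coefficients[2], bounds$lower[["kd"]] * 1.01),
             bounds$upper[["kd"]] * 0.99)
  A0 <- max(exp(ll$coefficients[1]), 1e-6)
  lo <- c(log(A0) - 10, log(bounds$lower[["kd"]]))
  hi <- c(log(A0) + 10, log(bounds$upper[["kd"]]))
  fn <- function(th) obs - (curve$baseline + exp(th[1]) * exp(-exp(th[2]) * dt))
  f <- minpack.lm::nls.lm(c(log(A0), log(kd0)), lower = lo, upper = hi,
                          fn = fn,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200, ftol = 1e-10, ptol = 1e-8))
  kd <- exp(f$par[2])
  list(kd = unname(kd), amplitude = unname(exp(f$par[1])), ssr = f$deviance,
       degenerate = unname(at_bound(f$par[2], lo[2], hi[2])))
}

# Build the stage-3 residual function over co-culture wells.
# `free` names the parameters optimized (log-scale theta); all others come
# from `fixed_params`. Returns list(fn, index data) used by the fitter and
# by sensitivity analyses.
stage3_objective <- function(coculture, fixed_params, curve, protocol,
                             t_add, te, engine = "compiled") {
  dt <- protocol$sampling_interval
  t2 <- seq(t_add, protocol$total_duration, by = dt)
  ratios <- sort(unique(coculture$et_ratio))
  nr <- length(ratios)
  T_add <- logistic_solution(t_add, fixed_params[["kp1"]],
                             fixed_params[["CT"]], protocol$target_seed)
  y0 <- as.vector(vapply(ratios, function(r) {
    E <- r * protocol$target_seed
    c(T_add, te * E, (1 - te) * E)
  }, numeric(3)))

  d <- dplyr::filter(coculture, .data$time_h >= t_add - 1e-9)
  ti <- match(round(d$time_h, 9), round(t2, 9))
  ki <- match(d$et_ratio, ratios)
  if (any(is.na(ti)) || any(is.na(ki))) {
    stop("coculture readings off the protocol grid", call. = FALSE)
  }
  obs <- d$ci
  base <- unclass(fixed_params)[param_names()]

  predict_ci <- function(params) {
    out <- integrate_states(params, y0, t2, engine = engine)
    ci <- matrix(0, length(t2), nr)
    for (k in seq_len(nr)) {
      ci[, k] <- curve$baseline + curve$target_slope * out[, 3 * k - 2] +
        curve$effector_slope * (out[, 3 * k - 1] + out[, 3 * k])
    }
    ci
  }
  make_params <- function(theta, free) {
    p <- base
    p[free] <- exp(theta)
    structure(p, class = "cart_params")
  }
  resid_fn <- function(theta, free) {
    ci <- predict_ci(make_params(theta, free))
    obs - ci[cbind(ti, ki)]
  }
  ssr_at <- function(params) {
    ci <- predict_ci(structure(unclass(params)[param_names()],
                               class = "cart_params"))
    sum((obs - ci[cbind(ti, ki)])^2)
  }
  list(resid_fn = resid_fn, ssr_at = ssr_at, make_params = make_params,
       predict_ci = predict_ci, t2 = t2, ratios = ratios, obs = d)
}

#' Stage 3: effector parameters from co-culture assays
#'
#' Estimates `kc, Kmr, n, kp2, Kmp, CE` by minimizing the unweighted sum
#' of squared residuals between model CI (forward simulation mapped
#' through the calibration) and the observed CI over all co-culture wells
#' and post-addition timepoints jointly. `n_starts` initial guesses are
#' drawn uniformly within the bounds and each is refined by bounded
#' Levenberg-Marquardt least squares on the log-parameter scale; the
#' minimum-SSR start wins (ties broken by the smaller bounds-normalized
#' parameter norm, then the lower start index), and the winner is polished
#' with a generous iteration cap. Identifiability of `Kmr` and `n`
#' requires co-cultures at two or more distinct E:T ratios.
#'
#' @param dataset A [cart_product()] on the working (normalized) scale.
#' @param fixed Named list/vector with stage-1/2 estimates `kp1`, `CT`,
#'   `kd`.
#' @param curve A [calibration_curve()].
#' @param config A [fit_config()].
#' @param addition_time Effector-addition time; resolved from the dataset
#'   if `NULL`.
#' @return A `cart_fit` object; see [fit_product()].
#' @export
fit_coculture <- function(dataset, fixed, curve, config = fit_config(),
                          addition_time = NULL) {
  cc <- dplyr::filter(dataset$traces, .data$condition == "coculture")
  if (nrow(cc) == 0) stop("stage 3: no coculture traces", call. = FALSE)
  ratios <- sort(unique(cc$et_ratio))
  weakly_identified <- length(ratios) < 2
  if (weakly_identified) {
    warning("fewer than 2 E:T ratios: Kmr and n are weakly identified")
  }
  t_add <- resolve_addition_time(dataset,
                                 declared = addition_time %||% dataset$addition_time)
  protocol <- config$protocol
  protocol$et_ratios <- ratios
  protocol$effector_addition_time <- t_add
  protocol$transduction_efficiency <- dataset$te

  fixed_params <- structure(
    c(kp1 = fixed[["kp1"]], CT = fixed[["CT"]], kc = 1e-2, Kmr = 1, n = 1,
      kp2 = 1e-2, Kmp = 1e2, CE = 1e6, kd = fixed[["kd"]]),
    class = "cart_params")
  free <- c("kc", "Kmr", "n", "kp2", "Kmp", "CE")
  obj <- stage3_objective(cc, fixed_params, curve, protocol, t_add,
                          dataset$te, engine = config$engine)

  lo <- log(config$bounds$lower[free])
  hi <- log(config$bounds$upper[free])
  # starts drawn uniformly on the log scale, covering the bounded
  # magnitude range evenly (bounds span several decades)
  set.seed(config$seed)
  u <- matrix(stats::runif(config$n_starts * length(free)),
              ncol = length(free), byrow = TRUE)
  starts <- exp(sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))

  ssr <- rep(Inf, config$n_starts)
  conv <- logical(config$n_starts)
  pars <- matrix(NA_real_, config$n_starts, length(free),
                 dimnames = list(NULL, free))
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                     ftol = 1e-10, ptol = 1e-8)
  for (i in seq_len(config$n_starts)) {
    f <- tryCatch(
      minpack.lm::nls.lm(log(starts[i, ]), lower = lo, upper = hi,
                         fn = obj$resid_fn, free = free, control = ctrl),
      error = function(e) NULL)
    if (is.null(f)) next
    ssr[i] <- f$deviance
    conv[i] <- f$info %in% 1:4
    pars[i, ] <- f$par
  }
  if (!any(is.finite(ssr))) {
    stop("stage 3: all multi-start fits failed", call. = FALSE)
  }
  # minimum SSR; ties -> smaller bounds-normalized norm, then lower index
  tol <- 1e-12 * max(min(ssr), .Machine$double.eps)
  cand <- which(ssr <= min(ssr) + tol)
  if (length(cand) > 1) {
    nrm <- apply(pars[cand, , drop = FALSE], 1,
                 function(p) sqrt(sum(((p - lo) / (hi - lo))^2)))
    cand <- cand[order(nrm, cand)]
  }
  best <- cand[1]
  # polish the leading candidates to full convergence and keep the winner
  top <- utils::head(order(ssr), 3)
  top <- unique(c(best, top[is.finite(ssr[top])]))
  polished <- lapply(top, function(i) {
    minpack.lm::nls.lm(pars[i, ], lower = lo, upper = hi,
                       fn = obj$resid_fn, free = free,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300, ftol = 1e-10, ptol = 1e-8))
  })
  dev <- vapply(polished, `[[`, numeric(1), "deviance")
  keep <- which.min(dev)
  best <- top[keep]
  polish <- polished[[keep]]
  params <- obj$make_params(polish$par, free)

  structure(
    list(params = structure(params, class = "cart_params"),
         ssr = polish$deviance,
         start_ssr = ssr, start_converged = conv,
         start_pars = exp(pars),
         n_starts = config$n_starts, n_converged = sum(conv),
         best_start_index = best, seed = config$seed,
         weakly_identified = weakly_identified,
         calibration = curve, addition_time = t_add, protocol = protocol,
         stage_provenance = list(
           stage1 = c("kp1", "CT"), stage2 = "kd", stage3 = free),
         objective = obj),
    class = "cart_fit")
}

#' Goodness of fit in CI units
#'
#' `R^2 = 1 - SSR/SST` with the total sum of squares taken about the
#' observed mean of each scope; the overall value pools every scope.
#'
#' @param observed Tidy traces carrying `condition`, `et_ratio`, `ci`.
#' @param predicted Model CI aligned with the rows of `observed`.
#' @return List with `r2_by_condition` (tibble: scope, n, ssr, r2),
#'   `r2_overall`, and `ssr`. Zero-variance scopes get `NA` R-squared.
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(nrow(observed) == length(predicted))
  d <- dplyr::mutate(observed, .pred = predicted,
                     scope = dplyr::if_else(
                       .data$condition == "coculture",
                       paste0("coculture_", format_ratio(.data$et_ratio)),
                       .data$condition))
  by <- d |>
    dplyr::group_by(.data$scope) |>
    dplyr::summarise(
      n = dplyr::n(),
      ssr = sum((.data$ci - .data$.pred)^2),
      sst = sum((.data$ci - mean(.data$ci))^2),
      .groups = "drop") |>
    dplyr::mutate(r2 = dplyr::if_else(.data$sst > 0, 1 - .data$ssr / .data$sst,
                                      NA_real_)) |>
    dplyr::select("scope", "n", "ssr", "r2")
  sst_all <- sum((d$ci - mean(d$ci))^2)
  ssr_all <- sum((d$ci - d$.pred)^2)
  list(r2_by_condition = by,
       r2_overall = if (sst_all > 0) 1 - ssr_all / sst_all else NA_real_,
       ssr = ssr_all)
}

#' Fit one product end to end
#'
#' Runs the full staged pipeline on a product's raw traces: collective
#' 0-4 normalization, effector-addition resolution, linear calibration,
#' stage 1 (tumor growth from target controls), stage 2 (decay from
#' effector controls), stage 3 (multi-start co-culture fit), and a final
#' goodness-of-fit pass over all conditions.
#'
#' @param dataset A [cart_product()] with target-control, effector-control
#'   and co-culture traces.
#' @param config A [fit_config()].
#' @return A `cart_fit` with the nine-parameter estimate, SSR,
#'   per-condition and overall R-squared, multi-start provenance, the
#'   calibration used, and stage provenance.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_products = 1)
#' prod <- emit_traces(draw_product(cfg, 1), cfg)
#' fit <- fit_product(prod, fit_config(n_starts = 25, seed = 1))
#' glance(fit)
#' }
#' @export
fit_product <- function(dataset, config = fit_config()) {
  norm <- normalize_product(dataset)
  t_add <- resolve_addition_time(norm, declared = norm$addition_time)
  protocol <- config$protocol
  protocol$transduction_efficiency <- dataset$te
  curve <- fit_calibration(norm, protocol, baseline = config$baseline,
                           addition_time = t_add)
  tr <- norm$traces

  tc <- dplyr::filter(tr, .data$condition == "target_control")
  if (nrow(tc) == 0) stop("stage 1: no target_control traces", call. = FALSE)
  s1 <- fit_tumor_growth(tc, curve, config$bounds, protocol)

  ec <- dplyr::filter(tr, .data$condition == "effector_control")
  if (nrow(ec) == 0) stop("stage 2: no effector_control traces", call. = FALSE)
  s2 <- fit_effector_decay(ec, curve, config$bounds, t_add = t_add)

  fit <- fit_coculture(norm, fixed = c(kp1 = s1$kp1, CT = s1$CT, kd = s2$kd),
                       curve = curve, config = config,
                       addition_time = t_add)

  # goodness of fit across all three assay conditions
  p <- fit$params
  pred_tc <- curve$baseline +
    curve$target_slope * logistic_solution(tc$time_h, s1$kp1, s1$CT,
                                           protocol$target_seed)
  pred_ec <- ifelse(ec$time_h >= t_add - 1e-9,
                    curve$baseline +
                      s2$amplitude * exp(-s2$kd * (ec$time_h - t_add)),
                    curve$baseline)
  cc <- fit$objective$obs
  ci_mat <- fit$objective$predict_ci(p)
  ti <- match(round(cc$time_h, 9), round(fit$objective$t2, 9))
  ki <- match(cc$et_ratio, fit$objective$ratios)
  pred_cc <- ci_mat[cbind(ti, ki)]
  all_obs <- dplyr::bind_rows(tc, ec, cc)
  gof <- goodness_of_fit(all_obs, c(pred_tc, pred_ec, pred_cc))

  fit$r2_by_condition <- gof$r2_by_condition
  fit$r2_overall <- gof$r2_overall
  fit$stage1 <- s1
  fit$stage2 <- s2
  fit$product_id <- dataset$product_id
  fit$objective <- NULL  # drop closures to keep the object lean
  fit
}

#' @export
print.cart_fit <- function(x, ...) {
  cat("<cart_fit>", if (!is.null(x$product_id)) x$product_id, "\n")
  print(format(unclass(x$params), digits = 4), quote = FALSE)
  cat(sprintf("SSR %.4g | overall R2 %s | %d/%d starts converged (best #%d, seed %d)\n",
              x$ssr,
              ifelse(is.null(x$r2_overall), "-", sprintf("%.3f", x$r2_overall)),
              x$n_converged, x$n_starts, x$best_start_index, x$seed))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted product
#'
#' @param x A `cart_fit`.
#' @param ... Unused.
#' @return One row per parameter with the estimating stage.
#' @export
tidy.cart_fit <- function(x, ...) {
  stage <- rep(NA_character_, 9)
  names(stage) <- param_names()
  for (s in names(x$stage_provenance)) stage[x$stage_provenance[[s]]] <- s
  tibble::tibble(parameter = param_names(),
                 estimate = as.numeric(unclass(x$params)[param_names()]),
                 stage = unname(stage))
}

#' One-line fit summary
#'
#' @param x A `cart_fit`.
#' @param ... Unused.
#' @return A one-row tibble with SSR, overall R-squared and multi-start
#'   provenance.
#' @export
glance.cart_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr,
                 r2_overall = x$r2_overall %||% NA_real_,
                 n_starts = x$n_starts, n_converged = x$n_converged,
                 best_start_index = x$best_start_index, seed = x$seed)
}
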