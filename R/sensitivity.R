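#' One-at-a-time error sensitivity of the fitted model
#'
#' Perturbs each effector parameter (`kc`, `Kmr`, `n`, `kp2`, `Kmp`,
#' `CE`, `kd`) by the given relative factors around the supplied
#' estimates and records the change in the co-culture SSR. Large absolute
#' changes in error indicate parameters that are both identifiable and
#' influential; perturbations landing outside the bounds are still
#' evaluated but flagged.
#'
#' @param dataset A [cart_product()] on the working (normalized) scale.
#' @param params Fitted [cart_params()] (the baseline).
#' @param perturbations Relative perturbations (default +/-10%, 25%,
#'   50%).
#' @param curve A [calibration_curve()]; refit from the dataset when
#'   `NULL`.
#' @param protocol The [assay_protocol()].
#' @param bounds [param_bounds()] used only for the out-of-bounds flag.
#' @param parameters Parameters to perturb.
#' @return Tibble: `parameter`, `perturbation`, `baseline_ssr`,
#'   `delta_ssr`, `out_of_bounds`.
#' @export
error_sensitivity <- function(dataset, params,
                              perturbations = c(-0.5, -0.25, -0.1,
                                                0.1, 0.25, 0.5),
                              curve = NULL, protocol = assay_protocol(),
                              bounds = param_bounds(),
                              parameters = effector_param_names()) {
  params <- as_cart_params(params)
  protocol$transduction_efficiency <- dataset$te
  t_add <- resolve_addition_time(dataset, declared = dataset$addition_time)
  if (is.null(curve)) {
    curve <- fit_calibration(dataset, protocol, addition_time = t_add)
  }
  cc <- dplyr::filter(dataset$traces, .data$condition == "coculture")
  obj <- stage3_objective(cc, params, curve, protocol, t_add, dataset$te)
  baseline_ssr <- obj$ssr_at(params)
  grid <- tidyr::expand_grid(parameter = parameters,
                             perturbation = perturbations)
  grid |>
    dplyr::mutate(purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      p <- unclass(params)
      p[grid$parameter[i]] <- p[grid$parameter[i]] * (1 + grid$perturbation[i])
      oob <- p[grid$parameter[i]] < bounds$lower[grid$parameter[i]] ||
        p[grid$parameter[i]] > bounds$upper[grid$parameter[i]]
      ssr <- tryCatch(obj$ssr_at(structure(p, class = "cart_params")),
                      error = function(e) NA_real_)
      tibble::tibble(baseline_ssr = baseline_ssr,
                     delta_ssr = ssr - baseline_ssr,
                     out_of_bounds = oob)
    }))
}

#' Global one-at-a-time sensitivity over parameter and E:T grids
#'
#' Sweeps each effector parameter across its bounded range (log-spaced,
#' all other parameters held at the reference values) crossed with a grid
#' of initial E:T ratios, recording the percent tumor cytolysis reached
#' `horizon` hours after effector addition.
#'
#' @param params Reference [cart_params()].
#' @param bounds [param_bounds()] defining each parameter's sweep range.
#' @param et_grid E:T ratios (default 1:4 through 25:1).
#' @param horizon Hours after effector addition at which cytolysis is
#'   read (default 48).
#' @param n_values Sweep points per parameter.
#' @param protocol The [assay_protocol()].
#' @param parameters Parameters to sweep.
#' @return Tibble: `parameter`, `value`, `et_ratio`, `pct_cytolysis`
#'   (`NA` for failed simulations).
#' @export
global_sensitivity <- function(params, bounds = param_bounds(),
                               et_grid = c(0.25, 0.5, 1, 6.25, 12.5, 25),
                               horizon = 48, n_values = 7,
                               protocol = assay_protocol(),
                               parameters = effector_param_names()) {
  params <- as_cart_params(params)
  t_read <- protocol$effector_addition_time + horizon
  stopifnot(t_read <= protocol$total_duration)
  control <- simulate_assay(params, protocol, et_ratio = 0)
  purrr::map_dfr(parameters, function(pn) {
    vals <- exp(seq(log(bounds$lower[[pn]]), log(bounds$upper[[pn]]),
                    length.out = n_values))
    purrr::map_dfr(vals, function(v) {
      p <- unclass(params)
      p[pn] <- v
      p <- structure(p, class = "cart_params")
      purrr::map_dfr(et_grid, function(r) {
        pc <- tryCatch(
          percent_cytolysis(simulate_assay(p, protocol, et_ratio = r),
                            control, t_read),
          error = function(e) NA_real_)
        tibble::tibble(parameter = pn, value = v, et_ratio = r,
                       pct_cytolysis = pc)
      })
    })
  })
}

correlation_from_jacobian <- function(J, names) {
  fim <- crossprod(J)
  sv <- svd(fim)
  tol <- max(dim(fim)) * .Machine$double.eps * max(sv$d)
  singular <- any(sv$d < tol)
  dinv <- ifelse(sv$d < tol, 0, 1 / sv$d)
  cov <- sv$v %*% (dinv * t(sv$u))
  s <- sqrt(pmax(diag(cov), 0))
  denom <- outer(s, s)
  corr <- ifelse(denom > 0, cov / denom, 1)
  # degenerate directions show up as perfectly confounded pairs
  if (singular) {
    null_dir <- abs(sv$v[, sv$d < tol, drop = FALSE])
    involved <- rowSums(null_dir) > 1e-8
    corr[involved, involved] <- sign(corr[involved, involved] +
                                       (corr[involved, involved] == 0))
  }
  corr <- pmin(pmax(corr, -1), 1)
  diag(corr) <- 1
  corr <- (corr + t(corr)) / 2
  dimnames(corr) <- list(names, names)
  list(matrix = corr, singular = singular)
}

#' Parameter-correlation identifiability analysis
#'
#' Pairwise correlations among the effector parameters at the fitted
#' optimum. The default derives the covariance from the Gauss-Newton
#' (Fisher-information) approximation using a finite-difference Jacobian
#' of the co-culture residuals with respect to the log parameters; the
#' `"multistart"` alternative takes empirical correlations of the
#' converged multi-start solutions of a [fit_coculture()] result.
#' Pairs with \eqn{|r| > 0.80} are flagged as highly correlated and pairs
#' with \eqn{|r| > 0.93} (the conventional cut-off) as non-identifiable;
#' singular information matrices mark the involved pairs at \eqn{|r| = 1}.
#'
#' @param dataset A [cart_product()] on the working (normalized) scale.
#' @param params Fitted [cart_params()].
#' @param method `"fim"` (default) or `"multistart"`.
#' @param curve,protocol As in [error_sensitivity()].
#' @param fit A `cart_fit` (required for `method = "multistart"`).
#' @param parameters Parameters analyzed.
#' @param high,cutoff Flag thresholds (0.80 / 0.93).
#' @return Object of class `cart_corr`: list with `matrix`, `flags`
#'   (tibble of off-diagonal pairs with their flags), `method`,
#'   `singular`.
#' @export
parameter_correlation <- function(dataset, params,
                                  method = c("fim", "multistart"),
                                  curve = NULL,
                                  protocol = assay_protocol(), fit = NULL,
                                  parameters = effector_param_names(),
                                  high = 0.80, cutoff = 0.93) {
  method <- match.arg(method)
  params <- as_cart_params(params)
  if (method == "fim") {
    protocol$transduction_efficiency <- dataset$te
    t_add <- resolve_addition_time(dataset, declared = dataset$addition_time)
    if (is.null(curve)) {
      curve <- fit_calibration(dataset, protocol, addition_time = t_add)
    }
    cc <- dplyr::filter(dataset$traces, .data$condition == "coculture")
    obj <- stage3_objective(cc, params, curve, protocol, t_add, dataset$te)
    th0 <- log(unclass(params)[parameters])
    r0 <- obj$resid_fn(th0, parameters)
    h <- 1e-4
    J <- vapply(seq_along(parameters), function(j) {
      thp <- th0; thp[j] <- thp[j] + h
      thm <- th0; thm[j] <- thm[j] - h
      (obj$resid_fn(thp, parameters) - obj$resid_fn(thm, parameters)) / (2 * h)
    }, numeric(length(r0)))
    res <- correlation_from_jacobian(J, parameters)
  } else {
    if (is.null(fit)) {
      stop("method = 'multistart' needs a cart_fit with start results",
           call. = FALSE)
    }
    keep <- fit$start_converged & is.finite(fit$start_ssr)
    est <- fit$start_pars[keep, , drop = FALSE]
    est <- est[, intersect(parameters, colnames(est)), drop = FALSE]
    if (nrow(est) < 3) stop("too few converged starts", call. = FALSE)
    res <- list(matrix = stats::cor(log(est)), singular = FALSE)
  }
  m <- res$matrix
  nm <- colnames(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  flags <- tibble::tibble(
    parameter_a = nm[pairs[, 1]], parameter_b = nm[pairs[, 2]],
    r = m[pairs],
    high_correlation = abs(m[pairs]) > high,
    non_identifiable = abs(m[pairs]) > cutoff)
  structure(list(matrix = m, flags = flags, method = method,
                 singular = res$singular, high = high, cutoff = cutoff),
            class = "cart_corr")
}

#' @export
print.cart_corr <- function(x, ...) {
  cat("<cart_corr> method:", x$method,
      if (x$singular) "(singular information matrix)", "\n")
  print(round(x$matrix, 3))
  fl <- dplyr::filter(x$flags, .data$high_correlation)
  if (nrow(fl)) {
    cat("pairs with |r| >", x$high, ":\n")
    print(as.data.frame(fl), digits = 3)
  }
  invisible(x)
}

#' Tidy the correlation flags
#'
#' @param x A `cart_corr`.
#' @param ... Unused.
#' @return Tibble of parameter pairs with correlation and flags.
#' @export
tidy.cart_corr <- function(x, ...) x$flags

#' E:T ratio sweep of predicted cytolysis
#'
#' Forward-simulates the assay over a grid of initial E:T ratios and
#' reports percent cytolysis (and, through `curve`, the final CI) at
#' `horizon` hours after effector addition. Two summary ratios are
#' attached: the saturation ratio (smallest ratio within `sat_tol`
#' percentage points of the largest-ratio cytolysis, reported only when
#' killing is substantial) and the negligible ratio (largest ratio with
#' cytolysis below `negligible`).
#'
#' @param params A [cart_params()].
#' @param protocol The [assay_protocol()].
#' @param ratio_grid E:T ratios to sweep.
#' @param horizon Hours after effector addition (default 48).
#' @param curve Optional [calibration_curve()] used to report final CI.
#' @param sat_tol Saturation tolerance in percentage points (default 5).
#' @param negligible Cytolysis floor in percent (default 10).
#' @return Tibble of class `cart_et_sweep`: `et_ratio`,
#'   `pct_cytolysis`, `final_ci`; attributes `saturation_ratio` and
#'   `negligible_ratio` (either may be `NA`).
#' @export
et_sweep <- function(params, protocol = assay_protocol(),
                     ratio_grid = c(0.25, 0.5, 1, 2, 6.25, 12.5, 25),
                     horizon = 48, curve = NULL, sat_tol = 5,
                     negligible = 10) {
  params <- as_cart_params(params)
  t_read <- protocol$effector_addition_time + horizon
  stopifnot(t_read <= protocol$total_duration)
  ratio_grid <- sort(ratio_grid)
  control <- simulate_assay(params, protocol, et_ratio = 0)
  rows <- purrr::map_dfr(ratio_grid, function(r) {
    sim <- simulate_assay(params, protocol, et_ratio = r)
    i <- match(round(t_read, 9), round(sim$time_h, 9))
    tibble::tibble(
      et_ratio = r,
      pct_cytolysis = percent_cytolysis(sim, control, t_read),
      final_ci = if (is.null(curve)) NA_real_ else
        ci_from_cells(sim[i, ], curve))
  })
  top <- rows$pct_cytolysis[nrow(rows)]
  sat <- if (top >= negligible) {
    min(rows$et_ratio[rows$pct_cytolysis >= top - sat_tol])
  } else {
    NA_real_
  }
  neg <- if (any(rows$pct_cytolysis < negligible)) {
    max(rows$et_ratio[rows$pct_cytolysis < negligible])
  } else {
    NA_real_
  }
  structure(rows, class = c("cart_et_sweep", class(rows)),
            saturation_ratio = sat, negligible_ratio = neg)
}
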