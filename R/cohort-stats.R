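#' Group products by clinical outcome
#'
#' Builds the two-group labeling for a comparison scheme. The relapse
#' scheme is defined only among initial responders (non-responders are
#' excluded); disease-restricted analyses filter to the given disease
#' first.
#'
#' @param outcomes Tibble with columns `product_id`, `response_day28`,
#'   `response_day90`, `relapse_day180`, `crs`, `neurotoxicity`, and
#'   optionally `disease`.
#' @param scheme One of `"day28"`, `"day90"`, `"relapse180"`, `"crs"`,
#'   `"neurotox"`.
#' @param disease Optional disease label to filter to (e.g. `"DLBCL"`).
#' @param relapse_base Which initial responders define the relapse
#'   population: responders at `"either"` day (default), `"day28"`, or
#'   `"day90"`.
#' @return Tibble `product_id`, `group` (two levels); errors if either
#'   group is empty.
#' @export
assign_groups <- function(outcomes, scheme = c("day28", "day90",
                                               "relapse180", "crs",
                                               "neurotox"),
                          disease = NULL,
                          relapse_base = c("either", "day28", "day90")) {
  scheme <- match.arg(scheme)
  relapse_base <- match.arg(relapse_base)
  d <- outcomes
  if (!is.null(disease)) {
    d <- dplyr::filter(d, .data$disease == !!disease)
  }
  g <- switch(scheme,
    day28 = dplyr::transmute(d, .data$product_id,
                             group = .data$response_day28),
    day90 = dplyr::transmute(d, .data$product_id,
                             group = .data$response_day90),
    relapse180 = {
      resp <- switch(relapse_base,
        either = d$response_day28 == "R" | d$response_day90 == "R",
        day28 = d$response_day28 == "R",
        day90 = d$response_day90 == "R")
      d |>
        dplyr::filter(resp, !is.na(.data$relapse_day180)) |>
        dplyr::transmute(.data$product_id, group = .data$relapse_day180)
    },
    crs = dplyr::transmute(d, .data$product_id, group = .data$crs),
    neurotox = dplyr::transmute(d, .data$product_id,
                                group = .data$neurotoxicity))
  g <- dplyr::filter(g, !is.na(.data$group))
  if (dplyr::n_distinct(g$group) < 2) {
    stop("scheme '", scheme, "' produces an empty group", call. = FALSE)
  }
  g
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact null distribution when the combined sample is small (<= 12) and
#' tie-free; otherwise the normal approximation with tie and continuity
#' corrections. Two-sided p-values, no multiplicity adjustment.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @return List: `statistic` (the Mann-Whitney U for `group_a`),
#'   `p_value`, `exact`, `degenerate` (all values identical across both
#'   groups, in which case p = 1).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
rank_sum_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p_value = 1, exact = FALSE, degenerate = TRUE))
  }
  ties <- any(duplicated(pooled))
  exact <- (length(pooled) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact, degenerate = FALSE)
}

rank_biserial <- function(a, b) {
  u <- rank_sum_test(a, b)$statistic
  1 - 2 * u / (length(a) * length(b))
}

#' Nonparametric effect size with bootstrap confidence interval
#'
#' The default estimator is the magnitude of the rank-biserial
#' correlation, `|1 - 2U/(n1 n2)|`; alternatives are Cliff's delta
#' (signed) and the common-language effect size `U/(n1 n2)`. The
#' confidence interval is a nonparametric bootstrap percentile interval,
#' deterministic given `seed`.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param method `"rank_biserial"`, `"cliffs_delta"`, or
#'   `"common_language"`.
#' @param conf Confidence level (default 0.95).
#' @return List: `estimate`, `ci` (length-2 vector, `NULL` for
#'   degenerate groups), `method`, `degenerate`.
#' @export
effect_size <- function(group_a, group_b, n_boot = 2000, seed = 1,
                        method = c("rank_biserial", "cliffs_delta",
                                   "common_language"),
                        conf = 0.95) {
  method <- match.arg(method)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  est_fn <- switch(method,
    rank_biserial = function(a, b) abs(rank_biserial(a, b)),
    cliffs_delta = function(a, b) -rank_biserial(a, b),
    common_language = function(a, b) {
      rank_sum_test(a, b)$statistic / (length(a) * length(b))
    })
  est <- est_fn(group_a, group_b)
  if (length(unique(c(group_a, group_b))) == 1L) {
    return(list(estimate = 0, ci = NULL, method = method,
                degenerate = TRUE))
  }
  set.seed(seed)
  boots <- replicate(n_boot, {
    est_fn(sample(group_a, replace = TRUE),
           sample(group_b, replace = TRUE))
  })
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       method = method, degenerate = FALSE)
}

#' Rank correlation between parameters and product composition
#'
#' Spearman rank correlation (average ranks for ties) of each parameter
#' against a composition variable such as the CD4:CD8 ratio; two-sided
#' p-values, unadjusted.
#'
#' @param data Tibble with parameter columns and the composition column.
#' @param composition Name of the composition column.
#' @param parameters Parameter columns to correlate.
#' @return Tibble: `parameter`, `composition`, `rho`, `p_value`, `n`.
#' @export
composition_correlation <- function(data, composition = "cd4_cd8",
                                    parameters = effector_param_names()) {
  x <- data[[composition]]
  keep <- !is.na(x)
  x <- x[keep]
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("composition variable is constant", call. = FALSE)
  }
  purrr::map_dfr(parameters, function(pn) {
    y <- data[[pn]][keep]
    ct <- suppressWarnings(
      stats::cor.test(y, x, method = "spearman",
                      alternative = "two.sided"))
    tibble::tibble(parameter = pn, composition = composition,
                   rho = unname(ct$estimate), p_value = ct$p.value,
                   n = length(x))
  })
}

#' Compare estimated parameters across outcome groups
#'
#' For each comparison scheme and each effector parameter (tumor-control
#' parameters `kp1`, `CT` and the negligible-magnitude `kd` are
#' excluded), runs the two-sided rank-sum test and the bootstrap effect
#' size. Comparisons whose grouping fails (e.g. an empty group) are
#' recorded with the reason and skipped.
#'
#' @param params_table Tibble with `product_id` and parameter columns
#'   (fitted estimates, one row per product).
#' @param outcomes Outcome tibble (see [assign_groups()]).
#' @param schemes Comparison schemes to run.
#' @param parameters Parameters to compare (default `kc`, `Kmr`, `n`,
#'   `kp2`, `Kmp`, `CE`).
#' @param disease Optional disease restriction applied to every scheme.
#' @param relapse_base Passed to [assign_groups()].
#' @param n_boot,seed Bootstrap settings for [effect_size()].
#' @param p_adjust `"none"` (default, matching the unadjusted analysis)
#'   or `"BH"` for Benjamini-Hochberg across the emitted comparisons.
#' @return Tibble: `scheme`, `parameter`, `group_a`, `group_b`, `n_a`,
#'   `n_b`, `statistic`, `p_value`, `effect_size`, `ci_lo`, `ci_hi`,
#'   `note`.
#' @export
run_cohort_analysis <- function(params_table, outcomes,
                                schemes = c("day28", "day90", "relapse180",
                                            "crs", "neurotox"),
                                parameters = c("kc", "Kmr", "n", "kp2",
                                               "Kmp", "CE"),
                                disease = NULL,
                                relapse_base = "either",
                                n_boot = 2000, seed = 1,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  out <- purrr::map_dfr(schemes, function(sc) {
    g <- tryCatch(assign_groups(outcomes, sc, disease = disease,
                                relapse_base = relapse_base),
                  error = function(e) e)
    if (inherits(g, "error")) {
      return(tibble::tibble(scheme = sc, parameter = parameters,
                            group_a = NA_character_,
                            group_b = NA_character_,
                            n_a = NA_integer_, n_b = NA_integer_,
                            statistic = NA_real_, p_value = NA_real_,
                            effect_size = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_,
                            note = conditionMessage(g)))
    }
    d <- dplyr::inner_join(params_table, g, by = "product_id")
    lv <- sort(unique(d$group))
    purrr::map_dfr(parameters, function(pn) {
      a <- d[[pn]][d$group == lv[1]]
      b <- d[[pn]][d$group == lv[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(scheme = sc, parameter = pn,
                              group_a = lv[1], group_b = lv[2],
                              n_a = length(a), n_b = length(b),
                              statistic = NA_real_, p_value = NA_real_,
                              effect_size = NA_real_, ci_lo = NA_real_,
                              ci_hi = NA_real_,
                              note = "group too small"))
      }
      rs <- rank_sum_test(a, b)
      es <- effect_size(a, b, n_boot = n_boot, seed = seed)
      tibble::tibble(scheme = sc, parameter = pn,
                     group_a = lv[1], group_b = lv[2],
                     n_a = length(a), n_b = length(b),
                     statistic = rs$statistic, p_value = rs$p_value,
                     effect_size = es$estimate,
                     ci_lo = if (is.null(es$ci)) NA_real_ else es$ci[1],
                     ci_hi = if (is.null(es$ci)) NA_real_ else es$ci[2],
                     note = dplyr::case_when(
                       rs$degenerate ~ "degenerate: identical values",
                       TRUE ~ NA_character_))
    })
  })
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
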