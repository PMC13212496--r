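# Shared fixtures: all test data is generated in code.

# Coarser sampling grid keeps module tests fast; the acceptance suite uses
# the full 15-minute protocol.
fast_protocol <- function(...) {
  assay_protocol(sampling_interval = 0.5, ...)
}

fast_config <- function(n_products = 2, seed = 1, ...) {
  cohort_config(n_products = n_products, protocol = fast_protocol(),
                seed = seed, ...)
}

ref_with <- function(...) {
  p <- unclass(reference_params())
  ov <- c(...)
  p[names(ov)] <- ov
  cartkin:::as_cart_params(p)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments (tie-free data only).
enumerate_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# A hand-built product with exactly linear trace structure, for
# calibration arithmetic: target CI = base + ts * seed * growth(t),
# effectors add se * E at t_add.
linear_product <- function(ts = 2.5e-5, se = 1.25e-5, base = 0,
                           seed_cells = 4e4, t_add = 24, dt = 0.25,
                           growth_per_h = 0.01, ratios = c(1, 6.25, 25)) {
  times <- seq(0, 72, by = dt)
  tumor_ci <- base + ts * seed_cells * (1 + growth_per_h * times)
  rows <- list(tibble::tibble(product_id = "LIN", condition = "target_control",
                              et_ratio = NA_real_, replicate = 1L,
                              time_h = times, ci = tumor_ci))
  for (r in ratios) {
    ci <- tumor_ci + ifelse(times >= t_add, se * r * seed_cells, 0)
    rows <- c(rows, list(tibble::tibble(product_id = "LIN",
                                        condition = "coculture",
                                        et_ratio = r, replicate = 1L,
                                        time_h = times, ci = ci)))
  }
  ec <- tibble::tibble(product_id = "LIN", condition = "effector_control",
                       et_ratio = NA_real_, replicate = 1L,
                       time_h = times,
                       ci = base + ifelse(times >= t_add, se * 2.5e5, 0))
  cart_product(dplyr::bind_rows(c(rows, list(ec))), te = 0.25,
               effector_seed = 2.5e5, addition_time = t_add)
}
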