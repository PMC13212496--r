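#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: a cohort of
#' CAR-T products assayed with the standard two-phase impedance protocol.
#' Transduction efficiencies follow a truncated normal (mean 0.2487,
#' SD 0.0875, range 0.098-0.488); kinetic parameters are drawn from
#' lognormal priors centered on [reference_params()] and clamped to the
#' estimation bounds; impedance noise is multiplicative (CV 2%) plus
#' additive (SD 0.01 CI); and outcome labels are linked to the
#' ground-truth parameters through a logistic model on standardized
#' log(Kmp) (relapse up) and log(n) (relapse down, CRS down).
#'
#' @param n_products Cohort size (default 45).
#' @param te_mean,te_sd,te_range Truncated-normal transduction-efficiency
#'   distribution.
#' @param priors Tibble with columns `parameter`, `location` (median) and
#'   `sdlog`; defaults to [default_priors()].
#' @param noise_cv Multiplicative reading noise (coefficient of
#'   variation).
#' @param noise_sd Additive reading noise (CI units).
#' @param outcome_link List of logistic coefficients: `beta0` (relapse
#'   log-odds at average parameters), `beta_kmp`, `beta_n`, response base
#'   rates `base_day28`, `base_day90`, `base_crs`, `base_neurotox`, and
#'   `beta_crs_n` (CRS link on n).
#' @param cd4cd8_meanlog,cd4cd8_sdlog Lognormal CD4:CD8 ratio
#'   distribution.
#' @param cd4cd8_n_slope Downward tilt of cooperativity `n` with
#'   increasing CD4:CD8 (0 disables the link).
#' @param calibration Named list: nominal `target_slope`, `effector_slope`
#'   (CI/cell), `baseline` and per-product lognormal slope jitter
#'   `jitter_sdlog`.
#' @param effector_seed Effector cells in effector-control wells.
#' @param protocol The [assay_protocol()].
#' @param bounds [param_bounds()] used to clamp prior draws.
#' @param seed Cohort seed; product `i` derives its own stream from
#'   `(seed, i)`.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_products = 45,
                          te_mean = 0.2487, te_sd = 0.0875,
                          te_range = c(0.098, 0.488),
                          priors = default_priors(),
                          noise_cv = 0.02, noise_sd = 0.01,
                          outcome_link = list(beta0 = stats::qlogis(0.6),
                                              beta_kmp = 2, beta_n = 1,
                                              base_day28 = 0.82,
                                              base_day90 = 0.73,
                                              base_crs = 0.5,
                                              base_neurotox = 0.3,
                                              beta_crs_n = 1),
                          cd4cd8_meanlog = log(2), cd4cd8_sdlog = 0.6,
                          cd4cd8_n_slope = 0,
                          calibration = list(target_slope = 2.5e-5,
                                             effector_slope = 2e-6,
                                             baseline = 0,
                                             jitter_sdlog = 0.1),
                          effector_seed = 2.5e5,
                          protocol = assay_protocol(),
                          bounds = param_bounds(),
                          seed = 1) {
  stopifnot(n_products >= 0, noise_cv >= 0, noise_sd >= 0)
  if (any(priors$location < bounds$lower[priors$parameter]) ||
      any(priors$location > bounds$upper[priors$parameter])) {
    stop("prior locations must lie within the parameter bounds",
         call. = FALSE)
  }
  structure(list(n_products = n_products, te_mean = te_mean, te_sd = te_sd,
                 te_range = te_range, priors = priors, noise_cv = noise_cv,
                 noise_sd = noise_sd, outcome_link = outcome_link,
                 cd4cd8_meanlog = cd4cd8_meanlog,
                 cd4cd8_sdlog = cd4cd8_sdlog,
                 cd4cd8_n_slope = cd4cd8_n_slope,
                 calibration = calibration, effector_seed = effector_seed,
                 protocol = protocol, bounds = bounds, seed = seed),
            class = "cohort_config")
}

#' Default lognormal parameter priors
#'
#' Medians sit at [reference_params()]; the log-SDs are chosen to produce
#' the considerable product-to-product spread seen in patient cohorts
#' while keeping draws within the estimation bounds (draws are clamped).
#'
#' @return Tibble with columns `parameter`, `location`, `sdlog`.
#' @export
default_priors <- function() {
  ref <- unclass(reference_params())
  tibble::tibble(
    parameter = param_names(),
    location = as.numeric(ref[param_names()]),
    sdlog = c(kp1 = 0.12, CT = 0.25, kc = 0.35, Kmr = 0.35, n = 0.25,
              kp2 = 0.35, Kmp = 0.5, CE = 0.3, kd = 0.25)[param_names()]
  )
}

product_seed <- function(seed, index, offset = 0L) {
  (as.integer(seed) %% 100000L) * 20011L + as.integer(index) * 7L +
    as.integer(offset)
}

rtrunc_norm1 <- function(mean, sd, range) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

#' Draw one synthetic product's ground truth
#'
#' Deterministic given `(config$seed, index)`: kinetic parameters from
#' the lognormal priors (clamped to bounds), transduction efficiency from
#' the truncated normal, a CD4:CD8 ratio, optionally tilting `n` downward
#' with increasing CD4:CD8, and a per-product calibration curve with
#' jittered slopes.
#'
#' @param config A [cohort_config()].
#' @param index Product index (1-based).
#' @return List of class `synthetic_product` with `truth`
#'   ([cart_params()]), `te`, `cd4_cd8`, `calibration`, `product_id`.
#' @export
draw_product <- function(config, index) {
  set.seed(product_seed(config$seed, index))
  pr <- config$priors
  z <- stats::rnorm(nrow(pr))
  val <- pr$location * exp(pr$sdlog * z)
  names(val) <- pr$parameter
  te <- rtrunc_norm1(config$te_mean, config$te_sd, config$te_range)
  cd4_cd8 <- exp(stats::rnorm(1, config$cd4cd8_meanlog, config$cd4cd8_sdlog))
  if (config$cd4cd8_n_slope != 0) {
    zr <- (log(cd4_cd8) - config$cd4cd8_meanlog) / config$cd4cd8_sdlog
    val["n"] <- val["n"] * exp(-config$cd4cd8_n_slope * zr)
  }
  val <- pmin(pmax(val, config$bounds$lower[names(val)]),
              config$bounds$upper[names(val)])
  cal <- config$calibration
  jit <- exp(stats::rnorm(2, 0, cal$jitter_sdlog))
  structure(
    list(truth = structure(val[param_names()], class = "cart_params"),
         te = te, cd4_cd8 = cd4_cd8,
         calibration = calibration_curve(cal$target_slope * jit[1],
                                         cal$effector_slope * jit[2],
                                         cal$baseline),
         index = index, product_id = sprintf("P%03d", index)),
    class = "synthetic_product")
}

#' Emit noisy impedance traces for a synthetic product
#'
#' Simulates the target control, effector control, and co-cultures at the
#' protocol's E:T ratios from the product's ground truth, maps cell
#' counts through the product's calibration curve, and adds multiplicative
#' then additive reading noise independently per replicate well.
#'
#' @param product A [draw_product()] result.
#' @param config The [cohort_config()].
#' @return A [cart_product()] carrying the traces and product metadata.
#' @export
emit_traces <- function(product, config) {
  protocol <- config$protocol
  protocol$transduction_efficiency <- product$te
  curve <- product$calibration
  sims <- list(
    list(condition = "target_control", et_ratio = NA_real_,
         sim = simulate_assay(product$truth, protocol, et_ratio = 0)),
    list(condition = "effector_control", et_ratio = NA_real_,
         sim = {
           p0 <- protocol; p0$target_seed <- 0
           simulate_assay(product$truth, p0, et_ratio = 0,
                          effectors = config$effector_seed)
         })
  )
  for (r in protocol$et_ratios) {
    sims <- c(sims, list(list(condition = "coculture", et_ratio = r,
                              sim = simulate_assay(product$truth, protocol,
                                                   et_ratio = r))))
  }
  set.seed(product_seed(config$seed, product$index, offset = 1000000L))
  rows <- purrr::map_dfr(sims, function(s) {
    clean <- ci_from_cells(s$sim, curve)
    purrr::map_dfr(seq_len(protocol$replicates), function(rep) {
      noisy <- clean * (1 + stats::rnorm(length(clean), 0, config$noise_cv)) +
        stats::rnorm(length(clean), 0, config$noise_sd)
      tibble::tibble(product_id = product$product_id,
                     condition = s$condition, et_ratio = s$et_ratio,
                     replicate = rep, time_h = s$sim$time_h, ci = noisy)
    })
  })
  cart_product(rows, te = product$te, cd4_cd8 = product$cd4_cd8,
               effector_seed = config$effector_seed,
               addition_time = protocol$effector_addition_time,
               product_id = product$product_id)
}

#' Assign outcome labels linked to ground-truth parameters
#'
#' Day-28 and day-90 responses are drawn independently at the configured
#' base rates. Relapse through day 180 (defined among responders) follows
#' `plogis(beta0 + beta_kmp * z(log Kmp) - beta_n * z(log n))`, encoding
#' the directional findings that more responsive proliferation (lower
#' Kmp) and higher cooperativity (higher n) accompany durable responses.
#' CRS is tilted toward lower n; neurotoxicity is independent.
#'
#' @param truth Tibble with one row per product and columns `product_id`,
#'   `Kmp`, `n` (typically from [cohort_truth_table()]).
#' @param config A [cohort_config()].
#' @param seed Seed for the label draws (defaults to the cohort seed).
#' @return Tibble: `product_id`, `response_day28`, `response_day90`,
#'   `relapse_day180` (`NA` for non-responders), `crs`, `neurotoxicity`,
#'   plus the relapse probability used.
#' @export
assign_outcomes <- function(truth, config, seed = config$seed) {
  link <- config$outcome_link
  z <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  lp <- link$beta0 + link$beta_kmp * z(log(truth$Kmp)) -
    link$beta_n * z(log(truth$n))
  p_rel <- stats::plogis(lp)
  p_crs <- stats::plogis(stats::qlogis(link$base_crs) -
                           link$beta_crs_n * z(log(truth$n)))
  set.seed(product_seed(seed, 0L, offset = 2000000L))
  n <- nrow(truth)
  r28 <- stats::rbinom(n, 1, link$base_day28) == 1
  r90 <- stats::rbinom(n, 1, link$base_day90) == 1
  relapse <- stats::rbinom(n, 1, p_rel) == 1
  crs <- stats::rbinom(n, 1, p_crs) == 1
  neuro <- stats::rbinom(n, 1, link$base_neurotox) == 1
  responder <- r28 | r90
  tibble::tibble(
    product_id = truth$product_id,
    response_day28 = ifelse(r28, "R", "NR"),
    response_day90 = ifelse(r90, "R", "NR"),
    relapse_day180 = ifelse(responder, ifelse(relapse, "yes", "no"),
                            NA_character_),
    crs = ifelse(crs, "yes", "no"),
    neurotoxicity = ifelse(neuro, "yes", "no"),
    relapse_probability = p_rel)
}

#' Ground-truth parameter table of a cohort
#'
#' @param products List of [draw_product()] results.
#' @return Tibble with one row per product: `product_id`, the nine
#'   parameters, `te`, `cd4_cd8`.
#' @export
cohort_truth_table <- function(products) {
  purrr::map_dfr(products, function(p) {
    dplyr::bind_cols(tibble::tibble(product_id = p$product_id),
                     tibble::as_tibble(as.list(unclass(p$truth))),
                     tibble::tibble(te = p$te, cd4_cd8 = p$cd4_cd8))
  })
}

#' Generate a complete synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param emit If `TRUE` (default), emit noisy traces for every product;
#'   otherwise only ground truth and outcomes are produced (fast path for
#'   statistical simulations).
#' @return List with `truth` (tibble), `outcomes` (tibble), `products`
#'   (list of [cart_product()] with outcomes attached, or of
#'   `synthetic_product` when `emit = FALSE`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), emit = TRUE) {
  if (config$n_products < 1) stop("n_products must be >= 1", call. = FALSE)
  drawn <- purrr::map(seq_len(config$n_products),
                      function(i) draw_product(config, i))
  truth <- cohort_truth_table(drawn)
  outcomes <- assign_outcomes(truth, config)
  products <- if (emit) {
    purrr::map(drawn, function(d) {
      prod <- emit_traces(d, config)
      o <- outcomes[outcomes$product_id == d$product_id, ]
      prod$outcomes <- outcome_record(o$response_day28, o$response_day90,
                                      o$relapse_day180, o$crs,
                                      o$neurotoxicity)
      prod
    })
  } else {
    drawn
  }
  list(truth = truth, outcomes = outcomes, products = products,
       config = config)
}

#' CD4:CD8 enrichment scenario
#'
#' Clones one base product at fixed CD4:CD8 ratios (1:1, 4:1, 10:1 and
#' CD4-only), tilting the cooperativity `n` downward with the CD4
#' fraction according to `n_slope`, and emits each ratio's dataset
#' independently. The reading at the effector-addition timepoint is
#' discarded and reconstructed through [impute_addition_ci()] from the
#' matching effector-control replicate, mirroring how the missed
#' plate-handling timepoint is handled.
#'
#' @param config A [cohort_config()].
#' @param ratios CD4:CD8 ratios; `Inf` encodes CD4-only.
#' @param n_slope Fractional decrease of `n` as the CD4 fraction rises
#'   from 0.5 (1:1) to 1 (CD4-only); 0 leaves `n` identical across
#'   ratios.
#' @return List with `truth` (tibble incl. the per-ratio `n`) and
#'   `products` (one [cart_product()] per ratio).
#' @export
cd4cd8_scenario <- function(config = cohort_config(),
                            ratios = c(1, 4, 10, Inf), n_slope = 0.4) {
  base <- draw_product(config, 1)
  products <- list()
  truth <- list()
  for (j in seq_along(ratios)) {
    r <- ratios[j]
    f <- if (is.infinite(r)) 1 else r / (1 + r)  # CD4 fraction
    p <- base
    p$index <- j
    p$product_id <- sprintf("CD4CD8_%s",
                            ifelse(is.infinite(r), "1to0",
                                   paste0(r, "to1")))
    p$cd4_cd8 <- r
    p$truth["n"] <- base$truth[["n"]] * (1 - n_slope * (f - 0.5))
    prod <- emit_traces(p, config)
    t_add <- config$protocol$effector_addition_time
    for (rep in unique(prod$traces$replicate)) {
      ec <- dplyr::filter(prod$traces,
                          .data$condition == "effector_control",
                          .data$replicate == rep)
      for (ratio in stats::na.omit(unique(prod$traces$et_ratio))) {
        sel <- prod$traces$condition == "coculture" &
          prod$traces$replicate == rep &
          prod$traces$et_ratio == ratio
        cc <- prod$traces[sel, ]
        prod$traces[sel, ] <- impute_addition_ci(cc, ec, t_add)
      }
    }
    products[[j]] <- prod
    truth[[j]] <- tibble::tibble(product_id = p$product_id,
                                 cd4_cd8 = r, cd4_fraction = f,
                                 n = p$truth[["n"]])
  }
  list(truth = dplyr::bind_rows(truth), products = products)
}
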