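#' Reproducible cohort workflow
#'
#' Three file-based stages tie the pipeline into reproducible runs, each
#' stage writing tidy CSV (plus JSON metadata) that the next stage reads:
#' `run_generate()` writes a synthetic cohort, `run_fit()` fits every
#' product and writes the parameter table, and `run_analyze()` writes the
#' outcome comparisons and composition correlations. Every stage records
#' the seed and a configuration hash in `run_meta.json`; two runs with
#' the same inputs, configuration and seed produce byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the files written.
#' @export
run_generate <- function(config = cohort_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, emit = TRUE)
  files <- c()
  for (p in cohort$products) {
    f <- file.path(out_dir, paste0(p$product_id, ".csv"))
    write_product(p, f)
    files <- c(files, f)
  }
  truth_f <- file.path(out_dir, "truth.csv")
  readr::write_csv(cohort$truth, truth_f)
  out_f <- file.path(out_dir, "outcomes.csv")
  readr::write_csv(cohort$outcomes, out_f)
  meta_f <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(list(stage = "generate", seed = config$seed,
                            n_products = config$n_products,
                            config_hash = rlang::hash(config)),
                       meta_f, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(products = files, truth = truth_f, outcomes = out_f,
                 meta = meta_f))
}

#' @rdname run_generate
#' @param products List of [cart_product()] objects, or a directory
#'   written by `run_generate()`.
#' @param fit_cfg A [fit_config()].
#' @param out_path Optional CSV path for the parameter table.
#' @export
run_fit <- function(products, fit_cfg = fit_config(), out_path = NULL) {
  if (is.character(products)) {
    csvs <- setdiff(list.files(products, pattern = "\\.csv$",
                               full.names = TRUE),
                    file.path(products, c("truth.csv", "outcomes.csv")))
    products <- lapply(csvs, read_product)
  }
  rows <- purrr::map_dfr(products, function(p) {
    fit <- tryCatch(suppressWarnings(fit_product(p, fit_cfg)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message("fit failed for ", p$product_id, ": ",
              conditionMessage(fit))
      return(tibble::tibble(product_id = p$product_id,
                            error = conditionMessage(fit)))
    }
    message(sprintf("fit %s: SSR %.4g, overall R2 %.3f",
                    p$product_id, fit$ssr, fit$r2_overall))
    dplyr::bind_cols(
      tibble::tibble(product_id = p$product_id),
      tibble::as_tibble(as.list(unclass(fit$params))),
      glance(fit)[, c("ssr", "r2_overall", "n_starts", "n_converged",
                      "seed")])
  })
  if (!is.null(out_path)) {
    readr::write_csv(rows, out_path)
    jsonlite::write_json(
      list(stage = "fit", seed = fit_cfg$seed,
           n_starts = fit_cfg$n_starts,
           config_hash = rlang::hash(fit_cfg)),
      file.path(dirname(out_path), "run_meta_fit.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  rows
}

#' @rdname run_generate
#' @param params_table Parameter tibble (or CSV path) from `run_fit()`.
#' @param outcomes Outcome tibble (or CSV path).
#' @param seed Seed for the bootstrap effect sizes.
#' @export
run_analyze <- function(params_table, outcomes, out_dir = NULL,
                        seed = 1, ...) {
  if (is.character(params_table)) params_table <- read_params_table(params_table)
  if (is.character(outcomes)) {
    outcomes <- readr::read_csv(outcomes, col_types = readr::cols())
  }
  comparisons <- run_cohort_analysis(params_table, outcomes, seed = seed,
                                     ...)
  corr <- if ("cd4_cd8" %in% names(params_table) &&
              sum(!is.na(params_table$cd4_cd8)) >= 3) {
    composition_correlation(params_table)
  } else {
    NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    if (!is.null(corr)) {
      readr::write_csv(corr, file.path(out_dir, "composition_correlations.csv"))
    }
    jsonlite::write_json(list(stage = "analyze", seed = seed),
                         file.path(out_dir, "run_meta_analyze.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(comparisons = comparisons, composition = corr)
}
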