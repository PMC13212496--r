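#' Read and write tidy impedance traces
#'
#' Traces travel as plain CSV with columns `product_id`, `condition`,
#' `et_ratio`, `replicate`, `time_h`, `ci`; metadata and outcomes travel
#' in a JSON sidecar (see [write_product()]). Round trips preserve values
#' to the full printed double precision.
#'
#' @param traces Tidy trace tibble.
#' @param path File path.
#' @return `read_traces()` returns the tibble; `write_traces()` returns
#'   `path` invisibly.
#' @export
write_traces <- function(traces, path) {
  validate_traces(traces)
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tr <- readr::read_csv(path, col_types = readr::cols(
    product_id = readr::col_character(),
    condition = readr::col_character(),
    et_ratio = readr::col_double(),
    replicate = readr::col_integer(),
    time_h = readr::col_double(),
    ci = readr::col_double()))
  validate_traces(tr)
  tr
}

#' Write / read a product with its metadata sidecar
#'
#' @param product A [cart_product()].
#' @param csv_path Trace CSV path.
#' @param json_path Metadata JSON path (defaults to the CSV path with a
#'   `.json` extension).
#' @return `read_product()` returns the [cart_product()];
#'   `write_product()` returns the paths invisibly.
#' @export
write_product <- function(product, csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  write_traces(product$traces, csv_path)
  meta <- list(product_id = product$product_id, te = product$te,
               cd4_cd8 = product$cd4_cd8, disease = product$disease,
               manufacturing_days = product$manufacturing_days,
               effector_seed = product$effector_seed,
               addition_time = product$addition_time,
               outcomes = if (is.null(product$outcomes)) NULL else
                 unclass(product$outcomes))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(c(csv_path, json_path))
}

#' @rdname write_product
#' @export
read_product <- function(csv_path,
                         json_path = sub("\\.csv$", ".json", csv_path)) {
  traces <- read_traces(csv_path)
  meta <- jsonlite::read_json(json_path)
  out <- if (is.null(meta$outcomes)) NULL else {
    o <- meta$outcomes
    outcome_record(o$response_day28 %||% NA_character_,
                   o$response_day90 %||% NA_character_,
                   o$relapse_day180 %||% NA_character_,
                   o$crs %||% NA_character_,
                   o$neurotoxicity %||% NA_character_,
                   o$disease %||% NA_character_)
  }
  cart_product(traces, te = meta$te,
               cd4_cd8 = meta$cd4_cd8 %||% NA_real_,
               disease = meta$disease %||% NA_character_,
               manufacturing_days = meta$manufacturing_days %||% NA_real_,
               outcomes = out,
               effector_seed = meta$effector_seed %||% NA_real_,
               addition_time = meta$addition_time %||% NA_real_,
               product_id = meta$product_id)
}

#' Serialize a simulation result
#'
#' Tidy CSV (`time_h`, `T`, `CART`, `TC`, `condition`, `et_ratio`) or
#' JSON with the protocol and parameters embedded.
#'
#' @param sim A `cart_sim` from [simulate_assay()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param condition Condition label recorded in the output.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, format = c("csv", "json"),
                             condition = "coculture") {
  format <- match.arg(format)
  et <- attr(sim, "et_ratio")
  tab <- dplyr::mutate(tibble::as_tibble(sim), condition = condition,
                       et_ratio = et)
  if (format == "csv") {
    readr::write_csv(tab, path)
  } else {
    jsonlite::write_json(
      list(protocol = unclass(attr(sim, "protocol")),
           params = as.list(unclass(attr(sim, "params"))),
           et_ratio = et, trajectory = tab),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and write per-product parameter tables
#'
#' One row per product with the nine parameter estimates plus fit
#' provenance columns.
#'
#' @param table Parameter tibble.
#' @param path CSV path.
#' @return `read_params_table()` returns the tibble.
#' @export
write_params_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_params_table
#' @export
read_params_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    product_id = readr::col_character(),
    .default = readr::col_double()))
}
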