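#' Impedance traces in tidy form
#'
#' Throughout the package a set of impedance traces is a tidy tibble with
#' one row per reading and columns `product_id`, `condition` (one of
#' `"target_control"`, `"effector_control"`, `"coculture"`,
#' `"positive_control"`), `et_ratio` (`NA` unless co-culture), `replicate`,
#' `time_h`, and `ci`. `validate_traces()` checks this contract.
#'
#' @param traces A tibble of impedance readings.
#' @return The traces, invisibly, after validation.
#' @export
validate_traces <- function(traces) {
  need <- c("product_id", "condition", "et_ratio", "replicate", "time_h", "ci")
  miss <- setdiff(need, names(traces))
  if (length(miss)) {
    stop("traces are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- c("target_control", "effector_control", "coculture", "positive_control")
  if (!all(traces$condition %in% ok)) {
    stop("condition must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(traces$ci))) stop("ci values must be finite", call. = FALSE)
  bad <- traces$condition != "coculture" & !is.na(traces$et_ratio)
  if (any(bad)) {
    stop("et_ratio must be NA for non-coculture conditions", call. = FALSE)
  }
  mono <- traces |>
    dplyr::group_by(.data$product_id, .data$condition, .data$et_ratio,
                    .data$replicate) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_h, strictly = TRUE),
                     .groups = "drop")
  if (!all(mono$ok)) {
    stop("times must be strictly increasing within each well", call. = FALSE)
  }
  invisible(traces)
}

#' One CAR-T product's assay data and metadata
#'
#' Bundles a product's impedance traces with its manufacturing metadata
#' and (optionally) the patient's clinical outcomes.
#'
#' @param traces Tidy trace tibble (see [validate_traces()]).
#' @param te Transduction efficiency, fraction in (0, 1].
#' @param cd4_cd8 CD4:CD8 ratio of the product, or `NA`.
#' @param disease Disease label (e.g. `"DLBCL"`, `"MCL"`, `"FL"`,
#'   `"CLL"`), or `NA`.
#' @param manufacturing_days Days of product expansion, or `NA`.
#' @param outcomes An [outcome_record()] or `NULL`.
#' @param effector_seed Effector cells seeded in effector-control wells
#'   (`NA` if unknown).
#' @param addition_time Declared effector-addition time in hours (`NA` to
#'   detect it from the traces).
#' @param product_id Identifier; defaults to the one in `traces`.
#' @return List of class `cart_product`.
#' @export
cart_product <- function(traces, te, cd4_cd8 = NA_real_,
                         disease = NA_character_,
                         manufacturing_days = NA_real_, outcomes = NULL,
                         effector_seed = NA_real_, addition_time = NA_real_,
                         product_id = NULL) {
  validate_traces(traces)
  if (!any(traces$condition == "target_control")) {
    stop("a product needs at least one target_control trace", call. = FALSE)
  }
  if (te <= 0 || te > 1) stop("te must be in (0, 1]", call. = FALSE)
  if (is.null(product_id)) product_id <- traces$product_id[1]
  structure(
    list(product_id = product_id, traces = tibble::as_tibble(traces),
         te = te, cd4_cd8 = cd4_cd8, disease = disease,
         manufacturing_days = manufacturing_days, outcomes = outcomes,
         effector_seed = effector_seed, addition_time = addition_time),
    class = "cart_product"
  )
}

#' @export
print.cart_product <- function(x, ...) {
  wells <- dplyr::distinct(x$traces, .data$condition, .data$et_ratio,
                           .data$replicate)
  cat("<cart_product> ", x$product_id, "\n",
      " wells: ", nrow(wells), " (",
      paste(table(wells$condition), names(table(wells$condition)),
            collapse = ", "), ")\n",
      " transduction efficiency: ", x$te, "\n", sep = "")
  if (!is.na(x$cd4_cd8)) cat(" CD4:CD8 ratio: ", x$cd4_cd8, "\n", sep = "")
  invisible(x)
}

#' Clinical outcome labels for one patient
#'
#' @param response_day28,response_day90 `"R"` (complete or partial
#'   response) or `"NR"` (progressive disease).
#' @param relapse_day180 `"yes"`/`"no"` among initial responders, `NA`
#'   (not applicable) for non-responders.
#' @param crs,neurotoxicity `"yes"`/`"no"`.
#' @param disease Disease label.
#' @return List of class `outcome_record`.
#' @export
outcome_record <- function(response_day28, response_day90,
                           relapse_day180 = NA_character_,
                           crs = NA_character_,
                           neurotoxicity = NA_character_,
                           disease = NA_character_) {
  chk <- function(x, lv) {
    if (!is.na(x) && !x %in% lv) {
      stop("value must be one of ", paste(lv, collapse = "/"), call. = FALSE)
    }
    x
  }
  structure(
    list(response_day28 = chk(response_day28, c("R", "NR")),
         response_day90 = chk(response_day90, c("R", "NR")),
         relapse_day180 = chk(relapse_day180, c("yes", "no")),
         crs = chk(crs, c("yes", "no")),
         neurotoxicity = chk(neurotoxicity, c("yes", "no")),
         disease = disease),
    class = "outcome_record"
  )
}
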