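#' Cytotoxicity assay protocol
#'
#' Describes the two-phase impedance assay: adherent targets seeded at time
#' zero and monitored alone, effectors added after `effector_addition_time`
#' hours, readings every `sampling_interval` hours until `total_duration`.
#' The defaults reproduce the standard protocol: 4e4 targets/well, effector
#' addition at 24 h, 15-minute readings over 72 h (289 readings/well), and
#' triplicate co-cultures at E:T ratios 1:1, 6.25:1 and 25:1.
#'
#' @param target_seed Target cells seeded per well.
#' @param effector_addition_time Hours after target seeding at which
#'   effectors are added.
#' @param total_duration Total assay duration in hours.
#' @param sampling_interval Hours between impedance readings; must divide
#'   both assay phases.
#' @param et_ratios Effector:target ratios of the co-culture conditions.
#' @param replicates Wells per condition.
#' @param transduction_efficiency Fraction of the effector pool expressing
#'   the CAR; splits effectors into CART and untransduced T cells.
#'
#' @return List of class `assay_protocol`.
#' @examples
#' p <- assay_protocol()
#' length(protocol_times(p))  # 289
#' @export
assay_protocol <- function(target_seed = 4e4,
                           effector_addition_time = 24,
                           total_duration = 72,
                           sampling_interval = 0.25,
                           et_ratios = c(1, 6.25, 25),
                           replicates = 3,
                           transduction_efficiency = 0.25) {
  stopifnot(target_seed >= 0, total_duration > 0, sampling_interval > 0,
            replicates >= 1)
  if (effector_addition_time <= 0 || effector_addition_time >= total_duration) {
    stop("effector_addition_time must lie strictly inside (0, total_duration)",
         call. = FALSE)
  }
  divides <- function(span) {
    k <- span / sampling_interval
    abs(k - round(k)) < 1e-9
  }
  if (!divides(effector_addition_time) ||
      !divides(total_duration - effector_addition_time)) {
    stop("sampling_interval must divide both assay phases", call. = FALSE)
  }
  if (any(et_ratios <= 0)) stop("et_ratios must be positive", call. = FALSE)
  if (transduction_efficiency <= 0 || transduction_efficiency > 1) {
    stop("transduction_efficiency must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(target_seed = target_seed,
         effector_addition_time = effector_addition_time,
         total_duration = total_duration,
         sampling_interval = sampling_interval,
         et_ratios = et_ratios,
         replicates = replicates,
         transduction_efficiency = transduction_efficiency),
    class = "assay_protocol"
  )
}

#' @export
print.assay_protocol <- function(x, ...) {
  cat("<assay_protocol>\n",
      " target seed:        ", x$target_seed, " cells\n",
      " effector addition:  ", x$effector_addition_time, " h\n",
      " duration / step:    ", x$total_duration, " h / ",
      x$sampling_interval, " h (", length(protocol_times(x)), " readings)\n",
      " E:T ratios:         ", paste(x$et_ratios, collapse = ", "), "\n",
      " replicates:         ", x$replicates, "\n",
      " transduction eff.:  ", x$transduction_efficiency, "\n", sep = "")
  invisible(x)
}

#' Sampling grid of an assay protocol
#'
#' @param protocol An [assay_protocol()].
#' @return Numeric vector of reading times in hours (includes time zero).
#' @export
protocol_times <- function(protocol) {
  seq(0, protocol$total_duration, by = protocol$sampling_interval)
}

#' Effector counts implied by the protocol's E:T ratios
#'
#' @param protocol An [assay_protocol()].
#' @return Named numeric vector of effector cells per co-culture condition.
#' @export
effector_counts <- function(protocol) {
  stats::setNames(protocol$et_ratios * protocol$target_seed,
                  format_ratio(protocol$et_ratios))
}

format_ratio <- function(r) {
  ifelse(r >= 1, paste0(format(r, trim = TRUE), ":1"),
         paste0("1:", format(1 / r, trim = TRUE)))
}
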