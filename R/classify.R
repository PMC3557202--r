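#' Qualitative classification of a mean trajectory
#'
#' Operationalizes the qualitative descriptions used for simulated
#' population curves. With deviation threshold `thr = up_threshold` around
#' the control state 1, an early checkpoint (default step 5) and the final
#' step:
#' \describe{
#'   \item{sustained}{mean `>= 1 + thr` at both the early and the final
#'     checkpoint (prolonged activation).}
#'   \item{transient}{mean `>= 1 + thr` early but `< 1 + thr` (possibly
#'     below control) at the end.}
#'   \item{suppressed}{mean `<= 1 - thr` at the end without an early
#'     elevation.}
#'   \item{unchanged}{anything else.}
#' }
#' The labels are mutually exclusive under these rules. A trajectory is
#' called *elevated* when its label is sustained or transient, i.e. it
#' shows an early response.
#'
#' @param mean_series numeric vector of per-step means, element 1 = step 0
#'   (e.g. one column of an ensemble's `mean` matrix).
#' @param up_threshold deviation threshold in state units (default 0.2).
#' @param early_step early checkpoint in steps (default 5).
#' @param final_step final checkpoint in steps; defaults to the last step
#'   of the series.
#' @return `trinet_label` object: list with `label`, `elevated`,
#'   `peak_step`, `peak_deviation`, `terminal_deviation`.
#' @examples
#' classify_trajectory(rep(1, 41))$label              # unchanged
#' classify_trajectory(c(1, rep(1.8, 10), rep(1, 30)))$label  # transient
#' @export
classify_trajectory <- function(mean_series, up_threshold = 0.2,
                                early_step = 5L, final_step = NULL) {
  stopifnot(up_threshold > 0)
  n_steps <- length(mean_series) - 1L
  if (is.null(final_step)) final_step <- n_steps
  if (final_step > n_steps || early_step > final_step) {
    stop("series too short for the requested checkpoints")
  }
  at <- function(s) mean_series[[s + 1L]]
  hi <- 1 + up_threshold
  lo <- 1 - up_threshold
  early_up <- at(early_step) >= hi
  final_v <- at(final_step)
  label <- if (early_up && final_v >= hi) {
    "sustained"
  } else if (early_up) {
    "transient"
  } else if (final_v <= lo) {
    "suppressed"
  } else {
    "unchanged"
  }
  dev <- mean_series - 1
  pk <- which.max(abs(dev))
  structure(list(label = label,
                 elevated = label %in% c("sustained", "transient"),
                 peak_step = pk - 1L,
                 peak_deviation = dev[[pk]],
                 terminal_deviation = final_v - 1),
            class = "trinet_label")
}

#' @export
print.trinet_label <- function(x, ...) {
  cat(sprintf("%s (peak %+0.2f at step %d, terminal %+0.2f)\n",
              x$label, x$peak_deviation, x$peak_step,
              x$terminal_deviation))
  invisible(x)
}
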