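#' Jump-fixed (step) cost of an activity level
#'
#' Evaluates the cumulative maintenance cost caused by an activity level
#' under an interval schedule: each interval with threshold `u` and price
#' `c` is triggered `floor(amount / u)` times, so the total is
#' `sum(floor(amount / threshold) * cost)`. The result is piecewise
#' constant and non-decreasing in `amount`, jumping exactly at integer
#' multiples of each threshold.
#'
#' @param amount Nonnegative activity level(s): starts, engine minutes or
#'   winch usages accumulated over the year. Vectorised.
#' @param intervals A tibble/data frame with columns `threshold` (strictly
#'   increasing, positive) and `cost` (nonnegative), e.g. one element of a
#'   [maintenance_schedule()].
#'
#' @return A numeric vector of costs in EUR, one per element of `amount`.
#' @examples
#' iv <- tibble::tibble(threshold = c(200, 400, 1200, 2400),
#'                      cost = c(4200, 8000, 50000, 100000))
#' step_cost(2584, iv)  # 298400
#' @export
step_cost <- function(amount, intervals) {
  if (any(amount < 0)) abort("activity amount must be nonnegative")
  if (nrow(intervals) == 0L) return(rep(0, length(amount)))
  if (any(intervals$threshold <= 0) || is.unsorted(intervals$threshold, strictly = TRUE)) {
    abort("interval thresholds must be strictly positive and strictly increasing")
  }
  if (any(intervals$cost < 0)) abort("interval costs must be nonnegative")
  triggered <- floor(outer(amount, intervals$threshold, `/`))
  as.numeric(triggered %*% intervals$cost)
}
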