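#' Engram membership from a recall trace
#'
#' The engram recruited by a recall probe is the set of neurons whose firing
#' rate reaches the active threshold at any sample inside the recall window
#' (the probe presentation, onset to onset + `window`). Ties count as active
#' (`>=`). Neurons recruited purely through recurrence, outside the cued
#' receptive field, qualify like any other.
#'
#' @param trace Rate matrix, one row per recorded time, one column per neuron.
#' @param times Sample times of the rows, ms.
#' @param onset Recall onset, ms.
#' @param window Membership window length, ms (the presentation duration).
#' @param theta Active threshold, Hz.
#' @return Sorted integer vector of member neuron indices.
#' @export
engram_members <- function(trace, times, onset, window, theta) {
  keep <- times >= onset - 1e-9 & times <= onset + window + 1e-9
  if (!any(keep)) stop("recall window lies outside the recorded trace",
                       call. = FALSE)
  peak <- apply(trace[keep, , drop = FALSE], 2, max)
  which(peak >= theta)
}

#' Memory-strength observer
#'
#' An ideal-observer proxy for the behavioural fear read-out: the summed
#' time-integral of every engram member's firing rate over the read-out
#' window starting at recall onset, evaluated with the trapezoidal rule on
#' the fine grid. Units Hz s. An empty engram gives 0.
#'
#' @inheritParams engram_members
#' @param members Engram member indices (see [engram_members()]).
#' @param window Read-out window length, ms.
#' @return The memory strength, Hz s.
#' @export
memory_strength <- function(trace, times, members, onset, window) {
  if (!length(members)) return(0)
  keep <- times >= onset - 1e-9 & times <= onset + window + 1e-9
  if (sum(keep) < 2) stop("read-out window lies outside the recorded trace",
                          call. = FALSE)
  tt <- times[keep] / 1000                     # ms -> s for Hz s units
  sub <- trace[keep, members, drop = FALSE]
  sum(vapply(seq_along(members), function(j) {
    y <- sub[, j]
    sum((y[-1] + y[-length(y)]) / 2 * diff(tt))
  }, 0))
}

#' Engram overlap
#'
#' Fraction of a reference engram reactivated by another recall:
#' `|A intersect B| / |A|`.
#'
#' @param ref Member indices of the reference engram (non-empty).
#' @param other Member indices of the comparison engram.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' engram_overlap(1:7, 5:10)  # 3/7
#' @export
engram_overlap <- function(ref, other) {
  if (!length(ref)) stop("reference engram is empty; overlap undefined",
                         call. = FALSE)
  length(intersect(ref, other)) / length(ref)
}

#' Runaway-rate exclusion check
#'
#' A trial is excluded when any neuron's firing rate reaches the exclusion
#' threshold (100 Hz by default) at any recorded time point.
#'
#' @param max_rate The maximum firing rate observed anywhere in the trial, Hz
#'   (scalar, or a full rate record to be reduced with `max()`).
#' @param threshold Exclusion threshold, Hz.
#' @return `TRUE` if the trial must be excluded.
#' @export
rate_limit_exceeded <- function(max_rate, threshold = 100) {
  max(max_rate) >= threshold
}
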