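#' Construct a raw acquisition trace
#'
#' One immersion of a sensor in a sample yields a potential-vs-time trace
#' (typically 120 s). Fingerprint analysis collapses the trace to a single
#' value once the sensor has equilibrated; see [collapse_trace()].
#'
#' @param sample_id sample identifier
#' @param sensor sensor channel name
#' @param t numeric vector of acquisition times in seconds, strictly
#'   increasing
#' @param potential numeric vector of readings, same length as `t`
#' @return object of class `signal_trace`
#' @export
signal_trace <- function(sample_id, sensor, t, potential) {
  t <- as.numeric(t)
  potential <- as.numeric(potential)
  if (length(t) != length(potential)) {
    stop("`t` and `potential` must have the same length")
  }
  if (length(t) < 1L) stop("empty trace")
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  structure(
    list(sample_id = as.character(sample_id), sensor = as.character(sensor),
         t = t, potential = potential),
    class = "signal_trace"
  )
}

#' Collapse an acquisition trace to its equilibrium reading
#'
#' Returns the arithmetic mean of the readings in the final `window_s`
#' seconds of the trace, i.e. samples with `t` in `(t_max - window_s, t_max]`
#' — the stage at which the sensor signal is most stable.
#'
#' @param trace signal_trace
#' @param window_s averaging window length in seconds (default 10)
#' @return single numeric value
#' @export
collapse_trace <- function(trace, window_s = 10) {
  stopifnot(inherits(trace, "signal_trace"))
  if (window_s <= 0) stop("`window_s` must be > 0")
  span <- trace$t[length(trace$t)] - trace$t[1L]
  if (span < window_s) {
    stop(sprintf("trace covers %.6g s, shorter than the %.6g s window",
                 span, window_s))
  }
  t_max <- trace$t[length(trace$t)]
  in_win <- trace$t > t_max - window_s & trace$t <= t_max
  mean(trace$potential[in_win])
}
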