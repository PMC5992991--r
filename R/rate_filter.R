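#' Exponential-kernel firing-rate estimate
#'
#' Per-neuron firing rates are estimated by low-pass filtering the spike train
#' with an exponential kernel: the rate \eqn{\lambda} decays as
#' \eqn{e^{-\Delta t/\tau}} between spikes and jumps by \eqn{1/\tau} (spikes/s)
#' at each spike. The default time constant is \eqn{\tau = 10} s. Between
#' events the update has a closed form, so the filter is advanced exactly,
#' event by event, with no per-step accumulation error.
#'
#' Rates are stored in spikes/s and times in ms; the conversion is internal.
#'
#' @param lambda initial rate (spikes/s), default 0.
#' @param tau filter time constant in seconds, default 10.
#' @param t_last time (ms) at which `lambda` was last valid, default 0.
#' @return object of class `rate_state`.
#' @examples
#' rs <- rate_state()
#' rs <- update_rate(rs, spike_times = 500, t_now = 1000)
#' rs$lambda  # 1/tau = 0.1 spikes/s, decayed 500 ms
#' @export
rate_state <- function(lambda = 0, tau = 10, t_last = 0) {
  stopifnot(lambda >= 0, tau > 0)
  structure(list(lambda = lambda, tau = tau, t_last = t_last),
            class = "rate_state")
}

#' Advance a rate filter through a set of spikes
#'
#' @param rs a [rate_state()].
#' @param spike_times spike times in ms, sorted, all in `(rs$t_last, t_now]`.
#' @param t_now time (ms) to advance to.
#' @return the updated `rate_state` with `t_last = t_now`.
#' @export
update_rate <- function(rs, spike_times, t_now) {
  stopifnot(inherits(rs, "rate_state"), t_now >= rs$t_last)
  tau_ms <- rs$tau * 1000
  if (length(spike_times)) {
    if (is.unsorted(spike_times)) stop("spike times must be sorted")
    if (spike_times[1] <= rs$t_last || spike_times[length(spike_times)] > t_now)
      stop("spike times must lie in (t_last, t_now]")
    lam <- rs$lambda
    t <- rs$t_last
    for (tf in spike_times) {
      lam <- lam * exp(-(tf - t) / tau_ms) + 1 / rs$tau
      t <- tf
    }
    rs$lambda <- lam * exp(-(t_now - t) / tau_ms)
  } else {
    rs$lambda <- rs$lambda * exp(-(t_now - rs$t_last) / tau_ms)
  }
  rs$t_last <- t_now
  rs
}

#' Binned-window firing-rate estimate
#'
#' Alternative estimator: the number of spikes in the trailing window divided
#' by the window length.
#'
#' @param spike_train spike times, ms.
#' @param window window length, ms (> 0).
#' @param t_end end of the window (ms); defaults to the last spike time
#'   (0 for an empty train).
#' @return rate in spikes/s.
#' @export
windowed_rate <- function(spike_train, window, t_end = NULL) {
  stopifnot(window > 0)
  if (!length(spike_train)) return(0)
  if (is.null(t_end)) t_end <- max(spike_train)
  n <- sum(spike_train > t_end - window & spike_train <= t_end)
  1000 * n / window
}
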