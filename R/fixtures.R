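#' Steering schedules for the six published two-population trajectories
#'
#' Returns the command schedule of one of the six narrated steering protocols
#' (A-F) for the two-population model, transcribed from their textual
#' description. All protocols start from the build default growth rate of
#' 0.0001 elements/ms (recorded in the `initial_nu` attribute). Growth-rate
#' commands target all element pools unless `element_type` is given
#' (which pools each change targeted is not stated; "all" is the default).
#'
#' Variant E is a different growth-curve *configuration* (inhibitory elements
#' only created above the target rate), not a sequence of runtime commands,
#' and returns an empty schedule. Variant B's update-interval step is narrated
#' without an explicit iteration (between its marks at 80 and 161); it is
#' placed at iteration 120.
#'
#' @param variant one of `"A"` ... `"F"`.
#' @param element_type optional element-type restriction for the commands.
#' @return a [command_log()] with attribute `initial_nu = 1e-4`.
#' @examples
#' make_steering_protocol("A")  # one command: iteration 8, nu = 5e-5
#' @export
make_steering_protocol <- function(variant = c("A", "B", "C", "D", "E", "F"),
                                   element_type = NA_character_) {
  variant <- match.arg(variant)
  nu <- function(when, value) {
    steering_command(when, "set_nu", element_type = element_type,
                     value = value)
  }
  log <- switch(variant,
    A = command_log(nu(8, 0.00005)),
    B = command_log(nu(38, 0.0010), nu(80, 0.0030),
                    steering_command(120, "set_update_interval", value = 500),
                    nu(161, 0.00005)),
    C = command_log(nu(46, 0.004), nu(98, 0.0018), nu(103, 0.0007)),
    D = command_log(nu(24, 0.001), nu(52, 0.0056), nu(78, 0.0020)),
    E = command_log(),
    F = command_log(nu(17, 0.002), nu(60, 0.00056), nu(80, 0.0002),
                    nu(90, 0.00005))
  )
  attr(log, "initial_nu") <- 1e-4
  log
}

#' Reproducible Poisson spike train
#'
#' Homogeneous Poisson process via exponential inter-spike intervals.
#'
#' @param rate rate, spikes/s (Hz).
#' @param duration duration, ms.
#' @param seed RNG seed.
#' @return sorted spike times in ms.
#' @export
make_poisson_train <- function(rate, duration, seed = 1) {
  stopifnot(rate >= 0, duration >= 0)
  set.seed(as.integer(seed))
  if (rate == 0 || duration == 0) return(numeric(0))
  # draw in blocks until past the horizon
  mean_isi_ms <- 1000 / rate
  times <- numeric(0)
  t <- 0
  repeat {
    n_blk <- max(16L, ceiling(1.5 * (duration - t) / mean_isi_ms))
    isi <- stats::rexp(n_blk, rate = rate / 1000)
    cs <- t + cumsum(isi)
    times <- c(times, cs[cs <= duration])
    t <- cs[length(cs)]
    if (t > duration) break
  }
  times
}
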