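#' Gaussian synaptic-element growth curve
#'
#' A growth curve maps a neuron's filtered firing rate \eqn{\lambda} to the
#' rate at which it creates or deletes synaptic elements (contact points).
#' The curve is parameterized by the minimal rate \eqn{\eta} below which
#' nothing happens (Heaviside cutoff), the target rate \eqn{\epsilon} at which
#' the curve crosses zero (the homeostatic set point), and the amplitude
#' \eqn{\nu} attained at the midpoint \eqn{(\eta+\epsilon)/2}:
#' \deqn{dn/dt = \nu\, H[\lambda-\eta]\,\left(2\cdot 2^{-\xi^2} - 1\right),
#'       \quad \xi = \frac{2(\lambda-\eta)}{\epsilon-\eta} - 1.}
#' With \eqn{\nu > 0} elements are created while \eqn{\eta < \lambda < \epsilon}
#' and deleted above \eqn{\epsilon}; a negative \eqn{\nu} inverts this, which
#' is the natural choice for inhibitory elements (inhibition is recruited when
#' activity exceeds the target).
#'
#' @param eta minimal firing rate (spikes/s); may be negative.
#' @param eps target firing rate (spikes/s); must exceed `eta`.
#' @param nu growth-rate amplitude (elements/ms); either sign.
#' @return an object of class `growth_curve`.
#' @examples
#' gc <- growth_curve(eta = 0, eps = 5, nu = 1e-4)
#' growth_rate(gc, c(0, 2.5, 5, 10))
#' @export
growth_curve <- function(eta, eps, nu) {
  stopifnot(is.numeric(eta), is.numeric(eps), is.numeric(nu),
            length(eta) == 1L, length(eps) == 1L, length(nu) == 1L,
            is.finite(nu))
  if (!(eps > eta)) {
    stop("invalid growth curve: target rate eps (", eps,
         ") must exceed minimal rate eta (", eta, ")")
  }
  structure(list(eta = eta, eps = eps, nu = nu), class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> eta = %g, eps = %g spikes/s, nu = %g elements/ms\n",
              x$eta, x$eps, x$nu))
  invisible(x)
}

#' Evaluate a growth curve
#'
#' @param curve a [growth_curve()].
#' @param lam firing rate(s), spikes/s; vectorized.
#' @return element growth rate(s), elements/ms.
#' @export
growth_rate <- function(curve, lam) {
  stopifnot(inherits(curve, "growth_curve"), is.numeric(lam), all(lam >= 0))
  growth_rate_num(lam, curve$eta, curve$eps, curve$nu)
}

# vectorized kernel shared with the pool integrator (parallel over all args)
growth_rate_num <- function(lam, eta, eps, nu) {
  xi <- 2 * (lam - eta) / (eps - eta) - 1
  h <- as.numeric(lam - eta >= 0)
  nu * h * (2 * 2^(-(xi^2)) - 1)
}

#' Integrate a synaptic-element pool over one interval
#'
#' Advances the continuous element count `z` of a pool by
#' `growth_rate(curve, lam) * dt`, clamping at zero. The integer `bound`
#' count (elements currently engaged in synapses) is untouched; reconciling
#' `floor(z)` against `bound` is the rewiring step's job.
#'
#' @param pool list with fields `z` (continuous count) and `bound` (integer).
#' @param curve a [growth_curve()].
#' @param lam filtered firing rate, spikes/s.
#' @param dt elapsed time, ms.
#' @return the pool with updated `z`.
#' @export
integrate_pool <- function(pool, curve, lam, dt) {
  stopifnot(dt > 0)
  pool$z <- max(0, pool$z + growth_rate(curve, lam) * dt)
  pool
}
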