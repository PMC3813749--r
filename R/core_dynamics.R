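#' Sigmoid (potential-to-rate) parameters
#'
#' Parameters of the origin-crossing sigmoid that converts an average
#' membrane potential deviation into an average firing-rate deviation.
#' The classical logistic of the Jansen-Rit lineage is shifted by its value
#' at `u = 0` so that the all-zero state of the circuit is a fixed point and
#' all state variables read as deviations from rest.
#'
#' @param e0 Half of the maximum firing rate (1/s). Must be positive.
#' @param r Slope of the sigmoid (1/V). Must be positive.
#' @param u0 Membrane potential at which half the maximum rate is reached
#'   (V). Must be positive.
#' @return An object of class `sigmoid_params`.
#' @seealso [sigmoid()], [sigmoid_max()]
#' @export
sigmoid_params <- function(e0 = 2.5, r = 560, u0 = 6e-3) {
  stopifnot(is.numeric(e0), length(e0) == 1L, e0 > 0,
            is.numeric(r), length(r) == 1L, r > 0,
            is.numeric(u0), length(u0) == 1L, u0 > 0)
  structure(list(e0 = e0, r = r, u0 = u0), class = "sigmoid_params")
}

#' Origin-crossing potential-to-rate sigmoid
#'
#' Computes `S(u) = 2 e0 / (1 + exp(r (u0 - u))) - 2 e0 / (1 + exp(r u0))`,
#' the logistic rate function shifted so that `S(0) = 0`. Negative outputs
#' are meaningful: they represent firing below the spontaneous baseline.
#'
#' @param u Membrane potential deviation (V); may be a vector.
#' @param p A [sigmoid_params()] object.
#' @return Firing-rate deviation(s) (1/s), same length as `u`.
#' @examples
#' sigmoid(0)                      # exactly 0
#' sigmoid(6e-3)                   # about 2.33 1/s at the half-activation point
#' @export
sigmoid <- function(u, p = sigmoid_params()) {
  stopifnot(inherits(p, "sigmoid_params"))
  if (any(!is.finite(u))) stop("non-finite membrane potential")
  2 * p$e0 / (1 + exp(p$r * (p$u0 - u))) - 2 * p$e0 / (1 + exp(p$r * p$u0))
}

#' Supremum of the sigmoid rate function
#'
#' The limit of [sigmoid()] as `u` grows without bound:
#' `2 e0 - 2 e0 / (1 + exp(r u0))`. Used as the maximum firing rate of a
#' neural mass, both for scaling the extrinsic input pulse and as the
#' normalizing rate `Q_max` in the vesicle-pool dynamics.
#'
#' @param p A [sigmoid_params()] object.
#' @return Maximum firing-rate deviation (1/s).
#' @export
sigmoid_max <- function(p = sigmoid_params()) {
  stopifnot(inherits(p, "sigmoid_params"))
  2 * p$e0 - 2 * p$e0 / (1 + exp(p$r * p$u0))
}

#' Alpha-kernel (rate-to-potential) parameters
#'
#' @param H Average synaptic gain (V); sets the kernel peak `H/e`.
#' @param tau Lumped time constant (s) of conduction, synaptic and dendritic
#'   delays; the kernel peaks at `t = tau`.
#' @return An object of class `alpha_kernel_params`.
#' @export
alpha_kernel_params <- function(H = 3.25e-3, tau = 10e-3) {
  stopifnot(is.numeric(H), length(H) == 1L, H > 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(H = H, tau = tau), class = "alpha_kernel_params")
}

#' Synaptic transform state
#'
#' One second-order synaptic transform carries a post-synaptic potential
#' contribution `y` and its time derivative `z`; `(0, 0)` is the rest state.
#'
#' @param y Post-synaptic potential contribution (V).
#' @param z Its time derivative (V/s).
#' @return An object of class `synapse_state`.
#' @export
synapse_state <- function(y = 0, z = 0) {
  stopifnot(is.finite(y), is.finite(z))
  structure(list(y = y, z = z), class = "synapse_state")
}

#' First-order form of the alpha kernel
#'
#' Right-hand side of the two coupled first-order ODEs equivalent to
#' convolution with the alpha kernel `h(t) = (H/tau) t exp(-t/tau)`:
#' `dy/dt = z`, `dz/dt = (H/tau) q - (2/tau) z - y/tau^2`.
#'
#' @param s A [synapse_state()] (or list with elements `y`, `z`).
#' @param q_in Input firing-rate deviation (1/s).
#' @param p An [alpha_kernel_params()] object.
#' @return Named numeric vector `c(dy, dz)`.
#' @export
kernel_rhs <- function(s, q_in, p) {
  stopifnot(inherits(p, "alpha_kernel_params"))
  c(dy = s$z,
    dz = (p$H / p$tau) * q_in - (2 / p$tau) * s$z - s$y / p$tau^2)
}

#' Alpha-kernel impulse response
#'
#' Closed form `h(t) = (H/tau) t exp(-t/tau)` for `t >= 0` (0 for `t < 0`,
#' causal kernel). Serves as the analytic oracle for integration tests of
#' [kernel_rhs()]: the response peaks at `t = tau` with value `H/e`.
#'
#' @param t Time(s) since the impulse (s); may be a vector.
#' @param p An [alpha_kernel_params()] object.
#' @return Potential(s) (V).
#' @export
kernel_impulse_response <- function(t, p) {
  stopifnot(inherits(p, "alpha_kernel_params"))
  ifelse(t < 0, 0, (p$H / p$tau) * t * exp(-t / p$tau))
}
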