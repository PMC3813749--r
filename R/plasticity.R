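#' Habituation (vesicle-pool) rate parameters
#'
#' Each habituating excitatory connection carries a two-state vesicle pool:
#' vesicles are either readily releasable (RR) or not (NRR). Presynaptic
#' activity moves vesicles out of the RR pool at rate
#' `n_depress * Q/Q_max`, and vesicles are recycled back at rate
#' `n_recover`. Each connection owns its own rate pair.
#'
#' @param n_depress Depression rate (1/s), >= 0. Default 20.
#' @param n_recover Recovery (recycling) rate (1/s), >= 0. Default 2, which
#'   lets a fully depleted pool return to 99% occupancy in about 2.3 s.
#' @return An object of class `habituation_params`.
#' @export
habituation_params <- function(n_depress = 20, n_recover = 2) {
  stopifnot(n_depress >= 0, n_recover >= 0)
  structure(list(n_depress = n_depress, n_recover = n_recover),
            class = "habituation_params")
}

#' Vesicle-pool occupancy dynamics
#'
#' Rate of change of the readily-releasable pool occupancy `A_RR`:
#' for non-negative presynaptic rate deviation `Q_pre`,
#' `dA/dt = n_recover (1 - A_RR) - n_depress (Q_pre/Q_max) A_RR`;
#' for negative `Q_pre` (firing below baseline) the process is recovery
#' only, `dA/dt = n_recover (1 - A_RR)`. The complementary occupancy is
#' `A_NRR = 1 - A_RR` by construction, so the two always sum to one. The
#' vector field points inward at both ends of [0, 1], so occupancy stays a
#' probability along any trajectory with `|Q_pre| <= Q_max`.
#'
#' @param A_RR Readily-releasable occupancy in `[0, 1]`; may be a vector.
#' @param Q_pre Presynaptic firing-rate deviation (1/s); may be a vector.
#' @param p A [habituation_params()] object.
#' @param Q_max Maximum firing rate (1/s) used to normalize `Q_pre`;
#'   defaults to [sigmoid_max()] of the default sigmoid.
#' @return `dA_RR/dt` (1/s).
#' @export
pool_rhs <- function(A_RR, Q_pre, p = habituation_params(),
                     Q_max = sigmoid_max()) {
  stopifnot(inherits(p, "habituation_params"))
  if (Q_max <= 0) stop("Q_max must be positive")
  stopifnot(all(A_RR >= 0 & A_RR <= 1))
  dep <- ifelse(Q_pre >= 0, p$n_depress * (Q_pre / Q_max) * A_RR, 0)
  p$n_recover * (1 - A_RR) - dep
}

#' Dynamic synaptic efficacy
#'
#' The efficacy `W` multiplying a connection's static strength is
#' proportional to the readily-releasable occupancy, with proportionality
#' constant fixed to 1 by the requirement that `W = 1` at the replete
#' (`A_RR = 1`) resting equilibrium.
#'
#' @param A_RR Occupancy in `[0, 1]`; may be a vector.
#' @return The efficacy `W` (dimensionless).
#' @export
efficacy <- function(A_RR) {
  stopifnot(all(A_RR >= 0 & A_RR <= 1))
  A_RR
}

#' Recovery time of a depleted pool
#'
#' Time for `A_RR` to rise from 0 to `target` under recovery alone
#' (`Q_pre <= 0`): the closed-form solution of the recovery branch is
#' `A_RR(t) = 1 - exp(-n_recover t)`, so the crossing time is
#' `-log(1 - target)/n_recover`. With the default recovery rate of 2 1/s
#' the pool reaches 99% occupancy in about 2.3 s.
#'
#' @param p A [habituation_params()] object.
#' @param target Target occupancy, strictly between 0 and 1.
#' @return Time (s); `Inf` (with a warning) when `n_recover` is 0.
#' @export
recovery_time <- function(p = habituation_params(), target = 0.99) {
  stopifnot(inherits(p, "habituation_params"), target > 0, target < 1)
  if (p$n_recover == 0) {
    warning("recovery rate is zero; the pool never recovers")
    return(Inf)
  }
  -log(1 - target) / p$n_recover
}
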