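#' Extrinsic input parameters
#'
#' The sensory afferent volley reaching the granular layer is modeled as a
#' gamma-shaped pulse per tone, `P0 ((t - t_k)/w)^n exp(-(t - t_k)/w)`,
#' summed over tone onsets `t_k`. Each pulse peaks at lag `n w` with value
#' `P0 n^n e^{-n}`. By default `P0` is chosen so that the pulse peak equals
#' the maximum firing rate of a neural mass (see [input_scale()]).
#'
#' @param w Input time constant (s); controls latency and dispersion.
#' @param n Shape exponent (dimensionless integer, default 7). Nearly
#'   redundant with `w` and the input gain, so it is held fixed during
#'   estimation.
#' @param P0 Scaling factor; if `NULL`, computed from `sigmoid`.
#' @param C1 Extrinsic connection strength scaling the pulse train.
#' @param sigmoid A [sigmoid_params()] object used to compute the default
#'   `P0`.
#' @return An object of class `input_params`.
#' @export
input_params <- function(w = 0.005, n = 7L, P0 = NULL, C1 = 50,
                         sigmoid = sigmoid_params()) {
  stopifnot(w > 0, n >= 1, C1 >= 0)
  if (is.null(P0)) P0 <- input_scale(sigmoid, n)
  stopifnot(P0 > 0)
  structure(list(w = w, n = as.integer(n), P0 = P0, C1 = C1),
            class = "input_params")
}

#' Scaling factor of the input pulse
#'
#' Computes `P0 = S_max / (n^n e^{-n})` where `S_max` is [sigmoid_max()],
#' so that a single input pulse peaks exactly at the maximum firing rate of
#' a neural mass. With the default sigmoid parameters and `n = 7` this
#' evaluates to about 0.0064.
#'
#' @param sigmoid A [sigmoid_params()] object.
#' @param n Shape exponent of the pulse.
#' @return The dimensionless scaling factor.
#' @export
input_scale <- function(sigmoid = sigmoid_params(), n = 7L) {
  sigmoid_max(sigmoid) / (n^n * exp(-n))
}

#' Tone-train timing
#'
#' @param n_tones Number of tones (>= 1).
#' @param onset_spacing Onset-to-onset interval (s). The default 0.5 s is
#'   a 15 ms tone followed by a 485 ms offset-to-onset gap.
#' @param t0 Onset time of the first tone (s).
#' @return An object of class `tone_train` with fields `onsets`, `count`,
#'   `spacing`.
#' @export
make_tone_train <- function(n_tones, onset_spacing = 0.5, t0 = 0) {
  stopifnot(n_tones >= 1)
  if (onset_spacing <= 0) stop("onset_spacing must be positive")
  structure(list(onsets = t0 + (seq_len(n_tones) - 1) * onset_spacing,
                 count = as.integer(n_tones),
                 spacing = onset_spacing),
            class = "tone_train")
}

#' Stimulation-paradigm description
#'
#' A paradigm is a set of identical tone sequences separated by silence.
#' Defaults mirror a standard auditory habituation protocol: sequences of
#' ten 15 ms tones with 485 ms offset-to-onset gaps (500 ms onset spacing),
#' sequences separated by 10 s of silence.
#'
#' @param n_sequences Number of sequences.
#' @param tones_per_sequence Tones per sequence.
#' @param tone_duration Tone duration (s).
#' @param offset_to_onset_gap Silence between a tone's offset and the next
#'   tone's onset (s).
#' @param inter_sequence_silence Silence between the last tone's offset and
#'   the next sequence's first onset (s).
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_sequences = 160L, tones_per_sequence = 10L,
                          tone_duration = 0.015, offset_to_onset_gap = 0.485,
                          inter_sequence_silence = 10) {
  stopifnot(n_sequences >= 0, tones_per_sequence >= 1, tone_duration > 0,
            offset_to_onset_gap > 0, inter_sequence_silence > 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 tones_per_sequence = as.integer(tones_per_sequence),
                 tone_duration = tone_duration,
                 offset_to_onset_gap = offset_to_onset_gap,
                 inter_sequence_silence = inter_sequence_silence),
            class = "paradigm_spec")
}

#' Expand a paradigm into tone trains
#'
#' @param spec A [paradigm_spec()].
#' @return A list of [make_tone_train()] objects, one per sequence, with the
#'   requested last-offset-to-first-onset silence between them.
#' @export
make_paradigm <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  spacing <- spec$tone_duration + spec$offset_to_onset_gap
  trains <- vector("list", spec$n_sequences)
  t0 <- 0
  for (i in seq_len(spec$n_sequences)) {
    tr <- make_tone_train(spec$tones_per_sequence, spacing, t0)
    trains[[i]] <- tr
    t0 <- tr$onsets[tr$count] + spec$tone_duration +
      spec$inter_sequence_silence
  }
  trains
}

#' Continuous input firing rate of a tone train
#'
#' Sum of gamma-shaped pulses over all onsets at or before `t`. Zero before
#' the first onset; non-negative and continuous everywhere. Contributions
#' from pulses older than the lag where they fall below 1e-12 of their peak
#' are truncated.
#'
#' @param t Time(s) (s); may be a vector.
#' @param train A [make_tone_train()] object or numeric vector of onsets.
#' @param p An [input_params()] object.
#' @return Input firing rate(s) (1/s).
#' @export
impulse_input <- function(t, train, p = input_params()) {
  stopifnot(inherits(p, "input_params"))
  onsets <- if (inherits(train, "tone_train")) train$onsets else train
  cutoff <- p$w * (p$n + 50)
  out <- numeric(length(t))
  for (tk in onsets) {
    x <- t - tk
    live <- x > 0 & x <= cutoff
    if (any(live)) {
      xw <- x[live] / p$w
      out[live] <- out[live] + p$P0 * xw^p$n * exp(-xw)
    }
  }
  out
}
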