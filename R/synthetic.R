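#' Draw latent parameters from the prior
#'
#' `theta ~ N(0, scale^2 * C_theta)` over the active rows of the prior
#' table; deterministic given `seed`.
#'
#' @param priors A prior table.
#' @param seed Integer RNG seed.
#' @param scale Multiplier on the latent prior standard deviations;
#'   `scale = 0` returns the prior mean (all zeros).
#' @return Named numeric latent vector.
#' @export
draw_parameters <- function(priors, seed = 1L, scale = 1) {
  stopifnot(scale >= 0)
  act <- active_priors(priors)
  set.seed(seed)
  th <- stats::rnorm(sum(act), 0, scale * sqrt(priors$var[act]))
  names(th) <- priors$name[act]
  th
}

#' Generate a synthetic source-waveform dataset
#'
#' Simulates the chosen circuit at the given ground-truth latent
#' parameters, observes the source waveform at the analysis rate,
#' max-normalizes it, and adds i.i.d. Gaussian noise. The default epoch
#' (-100 ms to 2500 ms, five tones at 500 ms onset spacing, 125 Hz)
#' matches the analysis epoch assumed by the inversion; the pre-stimulus
#' segment of the noise-free waveform is identically zero because the
#' circuit starts from rest.
#'
#' @param theta_true Named latent vector over the active priors (default:
#'   all zeros, i.e. prior expectations).
#' @param model `"LCCM"` or `"JRM"`.
#' @param train Tone train (default five tones, 500 ms spacing).
#' @param t_span Epoch (s).
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   the normalized waveform (>= 0).
#' @param seed Integer RNG seed for the noise.
#' @param dt Integration step (s).
#' @param fs Output sampling rate (Hz).
#' @param ... Passed to the model builder (e.g. `include_uncertain`).
#' @return An object of class `synthetic_dataset`: `waveform` (noisy),
#'   `clean` (noise-free normalized waveform), `theta_true`, `truth`
#'   (natural-scale parameters), `noise_sd`, `seed`, `model`, `train`,
#'   `t_span`, `priors`.
#' @export
generate_dataset <- function(theta_true = NULL, model = c("LCCM", "JRM"),
                             train = make_tone_train(5),
                             t_span = c(-0.1, 2.5), noise_sd = 0.05,
                             seed = 1L, dt = 1e-3, fs = 125, ...) {
  model <- match.arg(model)
  stopifnot(noise_sd >= 0)
  priors <- if (model == "LCCM") lccm_priors() else jrm_priors()
  builder <- if (model == "LCCM") build_lccm else build_jrm
  p <- sum(active_priors(priors))
  if (is.null(theta_true)) theta_true <- rep(0, p)
  if (!is.null(names(theta_true))) {
    th <- stats::setNames(rep(0, p), priors$name[active_priors(priors)])
    th[names(theta_true)] <- theta_true
    theta_true <- th
  } else {
    stopifnot(length(theta_true) == p)
    names(theta_true) <- priors$name[active_priors(priors)]
  }
  phi <- to_natural(theta_true, priors)
  m <- do.call(builder, c(list(phi), list(...)))
  wf <- observe(simulate_model(m, train, t_span, dt), fs = fs,
                normalize = TRUE)
  set.seed(seed)
  noisy <- wf
  noisy$y <- wf$y + stats::rnorm(length(wf$y), 0, noise_sd)
  structure(list(waveform = noisy, clean = wf, theta_true = theta_true,
                 truth = phi, noise_sd = noise_sd, seed = as.integer(seed),
                 model = model, train = train, t_span = t_span,
                 priors = priors),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %s, %d samples at %g Hz, noise sd %g, seed %d>\n",
              x$model, length(x$waveform$y), x$waveform$fs, x$noise_sd,
              x$seed))
  invisible(x)
}

#' Invert a synthetic dataset
#'
#' Convenience wrapper pairing [generate_dataset()] output with the
#' matching predictor and [em_gauss_newton()].
#'
#' @param dataset A `synthetic_dataset`.
#' @param model Model to fit (`"LCCM"` or `"JRM"`); defaults to the
#'   generating model.
#' @param opts Options passed to [em_gauss_newton()].
#' @param ... Passed to the model builder.
#' @return An `nmm_posterior`.
#' @export
invert_dataset <- function(dataset, model = dataset$model, opts = list(),
                           ...) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  priors <- if (model == "LCCM") lccm_priors() else jrm_priors()
  builder <- if (model == "LCCM") build_lccm else build_jrm
  h <- nmm_predictor(builder, priors, train = dataset$train,
                     t_span = dataset$t_span, fs = dataset$waveform$fs, ...)
  em_gauss_newton(dataset$waveform$y, h, priors, opts)
}

#' Parameter-recovery experiment
#'
#' Repeatedly draws ground-truth parameters, generates noisy synthetic
#' data, inverts them, and summarizes per-parameter bias, RMSE and 90%
#' credible-interval coverage of the latent truths.
#'
#' @param n_reps Number of replicates (>= 1).
#' @param noise_sd Noise level of the synthetic data.
#' @param seeds Integer seeds, one per replicate.
#' @param scale Latent prior-sd multiplier for the truth draws.
#' @param model `"LCCM"` or `"JRM"`.
#' @param opts Options passed to [em_gauss_newton()].
#' @param report_csv Optional path; when given, the per-parameter summary
#'   is written as CSV.
#' @return List with `per_draw` (long data frame of truth/estimate/sd per
#'   parameter and replicate) and `summary` (per-parameter bias, RMSE,
#'   coverage).
#' @export
recovery_experiment <- function(n_reps = 3L, noise_sd = 0.05,
                                seeds = seq_len(n_reps), scale = 0.25,
                                model = "LCCM", opts = list(),
                                report_csv = NULL) {
  stopifnot(n_reps >= 1, length(seeds) == n_reps)
  priors <- if (model == "LCCM") lccm_priors() else jrm_priors()
  rows <- list()
  for (i in seq_len(n_reps)) {
    th_true <- draw_parameters(priors, seed = seeds[i], scale = scale)
    ds <- generate_dataset(th_true, model = model, noise_sd = noise_sd,
                           seed = seeds[i] + 10000L)
    post <- invert_dataset(ds, opts = opts)
    rows[[i]] <- data.frame(rep = i, seed = seeds[i],
                            parameter = names(post$eta),
                            truth = as.numeric(th_true),
                            estimate = as.numeric(post$eta),
                            sd = as.numeric(post$sd),
                            stringsAsFactors = FALSE)
  }
  per_draw <- do.call(rbind, rows)
  z90 <- stats::qnorm(0.95)
  per_draw$covered <- abs(per_draw$truth - per_draw$estimate) <=
    z90 * per_draw$sd
  agg <- do.call(rbind, lapply(split(per_draw, per_draw$parameter),
    function(d) data.frame(parameter = d$parameter[1],
                           bias = mean(d$estimate - d$truth),
                           rmse = sqrt(mean((d$estimate - d$truth)^2)),
                           coverage = mean(d$covered),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  if (!is.null(report_csv))
    utils::write.csv(agg, report_csv, row.names = FALSE)
  list(per_draw = per_draw, summary = agg)
}

#' Inter-stimulus-interval suppression experiment
#'
#' Simulates five-tone trains at each requested onset spacing under the
#' prior-expected parameters and tabulates the habituation suppression,
#' `1 - peak(last tone)/peak(first tone)`. Shorter intervals leave the
#' vesicle pools less time to recover, so suppression decreases with ISI.
#'
#' @param isis Onset spacings to test (s), each >= 0.2.
#' @param n_tones Tones per train.
#' @param params Natural-scale model parameters.
#' @param dt Integration step (s).
#' @return Data frame sorted by ISI with columns `isi`, `peak_first`,
#'   `peak_last`, `suppression`.
#' @export
isi_experiment <- function(isis = c(0.5, 1.0, 1.5), n_tones = 5L,
                           params = prior_expectations(), dt = 1e-3) {
  stopifnot(all(isis >= 0.2))
  isis <- sort(isis)
  m <- build_lccm(params)
  out <- lapply(isis, function(isi) {
    train <- make_tone_train(n_tones, isi)
    t_end <- train$onsets[n_tones] + 0.5
    sim <- simulate_model(m, train, c(-0.1, t_end), dt)
    wf <- observe(sim, fs = 1 / dt)
    pk <- tone_peaks(wf, train, window = min(isi, 0.45))
    data.frame(isi = isi, peak_first = pk[1], peak_last = pk[n_tones],
               suppression = 1 - pk[n_tones] / pk[1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Probe-tone recovery scan
#'
#' Simulates a habituating tone train followed by a silent interval and a
#' single probe tone, for a grid of silent intervals, and reports the
#' probe-to-first-tone peak ratio. The attribute `recovered_at` gives the
#' smallest scanned interval at which the probe response is within `tol`
#' of the first-tone response.
#'
#' @param silences Silent intervals to scan (s), measured onset-to-onset
#'   minus the train spacing is not subtracted: the probe onset is the last
#'   train onset plus the scanned interval.
#' @param n_tones Tones in the habituating train.
#' @param spacing Train onset spacing (s).
#' @param params Natural-scale model parameters.
#' @param tol Relative tolerance on the peak ratio (default 1%).
#' @param dt Integration step (s).
#' @return Data frame with `silence`, `peak_first`, `peak_probe`, `ratio`;
#'   attribute `recovered_at` (smallest recovered interval, or `NA`).
#' @export
probe_recovery <- function(silences = seq(0.5, 10, by = 0.5),
                           n_tones = 10L, spacing = 0.5,
                           params = prior_expectations(), tol = 0.01,
                           dt = 1e-3) {
  m <- build_lccm(params)
  rows <- lapply(silences, function(Ts) {
    last_on <- (n_tones - 1) * spacing
    onsets <- c((seq_len(n_tones) - 1) * spacing, last_on + Ts)
    sim <- simulate_model(m, onsets, c(-0.1, last_on + Ts + 0.5), dt)
    wf <- observe(sim, fs = 1 / dt)
    pk <- tone_peaks(wf, c(0, last_on + Ts), window = min(spacing, 0.45))
    data.frame(silence = Ts, peak_first = pk[1], peak_probe = pk[2],
               ratio = pk[2] / pk[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  rec <- out$silence[out$ratio >= 1 - tol]
  attr(out, "recovered_at") <- if (length(rec)) min(rec) else NA_real_
  out
}
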