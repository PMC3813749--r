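#' Forward predictor for model inversion
#'
#' Builds the deterministic forward map `h(theta)` used by
#' [em_gauss_newton()]: latent parameters are mapped to natural scale,
#' the circuit is assembled and integrated, the source waveform is observed
#' at the analysis rate, scaled by the reference amplitude of the
#' prior-expected prediction, and multiplied by the free observation gain.
#' With this scaling the prediction at `theta = 0` has unit peak amplitude,
#' commensurate with max-normalized data, and the gain parameter only has
#' to absorb residual amplitude differences.
#'
#' @param builder Model builder taking a named natural-parameter vector
#'   (e.g. [build_lccm()] or [build_jrm()]).
#' @param priors Matching prior table.
#' @param train Tone train driving the model.
#' @param t_span Simulated epoch (s).
#' @param dt Integration step (s).
#' @param fs Observation sampling rate (Hz).
#' @param ... Further arguments passed to `builder`.
#' @return A function `h(theta)` returning the predicted waveform samples.
#' @export
nmm_predictor <- function(builder, priors, train = make_tone_train(5),
                          t_span = c(-0.1, 2.5), dt = 1e-3, fs = 125, ...) {
  force(builder); force(priors); force(train); force(t_span)
  force(dt); force(fs)
  extra <- list(...)
  raw <- function(theta) {
    phi <- to_natural(theta, priors)
    m <- do.call(builder, c(list(phi), extra))
    observe(simulate_model(m, train, t_span, dt), fs = fs)$y
  }
  s0 <- NULL
  function(theta) {
    if (is.null(s0)) {
      y0 <- raw(rep(0, sum(active_priors(priors))))
      m0 <- max(abs(y0))
      s0 <<- if (m0 > 0) m0 else 1
    }
    phi <- to_natural(theta, priors)
    phi[["gain"]] * raw(theta) / s0
  }
}

#' Laplace free energy (approximate log model evidence)
#'
#' `F = -||r||^2/(2 sigma2) - N/2 log(2 pi sigma2)
#'      - eta' C_theta^{-1} eta / 2 - log|C_theta|/2 + log|Sigma|/2`,
#' the Laplace approximation to the log evidence under i.i.d. Gaussian
#' observation noise `sigma2 I` and a diagonal Gaussian prior: an accuracy
#' term minus a complexity term that charges for posterior displacement
#' from the prior mean and for posterior precision gained from the data.
#' Differences of `F` between models are log Bayes factors.
#'
#' @param residual Data-minus-prediction residual vector at the posterior
#'   mean.
#' @param sigma2 Observation noise variance.
#' @param eta Posterior mean of the latent parameters.
#' @param prior_var Diagonal of the latent prior covariance.
#' @param Sigma Posterior covariance matrix (symmetric positive definite).
#' @return The free energy (scalar).
#' @export
laplace_free_energy <- function(residual, sigma2, eta, prior_var, Sigma) {
  N <- length(residual)
  logdet_post <- if (length(Sigma) == 0) 0 else {
    R <- tryCatch(chol(Sigma), error = function(e)
      stop("posterior covariance is not positive definite"))
    2 * sum(log(diag(R)))
  }
  -0.5 * sum(residual^2) / sigma2 - 0.5 * N * log(2 * pi * sigma2) -
    0.5 * sum(eta^2 / prior_var) - 0.5 * sum(log(prior_var)) +
    0.5 * logdet_post
}

fd_jacobian <- function(forward, theta, h0, step) {
  p <- length(theta)
  J <- matrix(0, length(h0), p)
  safe <- function(th) tryCatch(forward(th), error = function(e) NULL)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + step
    tm <- theta; tm[j] <- tm[j] - step
    hp <- safe(tp); hm <- safe(tm)
    if (!is.null(hp) && !is.null(hm)) J[, j] <- (hp - hm) / (2 * step)
    else if (!is.null(hp)) J[, j] <- (hp - h0) / step
    else if (!is.null(hm)) J[, j] <- (h0 - hm) / step
    else warning("forward model failed on both sides of parameter ", j,
                 "; treating derivative as zero")
  }
  J
}

solve_spd <- function(M, b = NULL, ridge = 1e-10) {
  out <- tryCatch({
    R <- chol(M)
    if (is.null(b)) chol2inv(R) else backsolve(R, forwardsolve(t(R), b))
  }, error = function(e) NULL)
  if (is.null(out)) {
    warning("normal equations near-singular; ridge-stabilized")
    M2 <- M + diag(ridge * max(diag(M), 1), nrow(M))
    R <- chol(M2)
    out <- if (is.null(b)) chol2inv(R) else
      backsolve(R, forwardsolve(t(R), b))
  }
  out
}

#' EM Gauss-Newton posterior estimation
#'
#' Maximum a posteriori estimation of the latent parameters of a nonlinear
#' forward model under diagonal Gaussian priors, with an EM update of the
#' observation-noise variance. Each iteration computes a finite-difference
#' Jacobian `J` of the forward map (E-step ingredients), updates the noise
#' variance `sigma2 <- (||r||^2 + tr(J Sigma J'))/N` (M-step), and takes a
#' damped Gauss-Newton step on the log joint
#' `eta <- eta + (J'J/sigma2 + C^-1)^{-1} (J'r/sigma2 - C^-1 eta)`,
#' halving the step while the log joint does not improve. Iteration stops
#' when the maximum absolute update falls below `tol` or after `max_iter`
#' iterations. The posterior covariance is the inverse Gauss-Newton
#' curvature at the final mean and the free energy is the Laplace
#' approximation of [laplace_free_energy()].
#'
#' @param y Observed waveform samples (numeric vector).
#' @param forward Forward map `h(theta)` returning a prediction of the same
#'   length as `y` (see [nmm_predictor()]); may `stop()` on blow-up, which
#'   is treated as a rejected step.
#' @param priors Prior table; only non-`const` rows are estimated.
#' @param opts List of options: `max_iter` (64), `tol` (1e-4), `fd_step`
#'   (1e-3), `sigma2` (initial noise variance; default from the initial
#'   residual), `update_sigma2` (TRUE), `sigma2_min` (1e-10), `init`
#'   (initial latent vector, default prior mean 0), `max_halvings` (8),
#'   `ridge` (1e-10).
#' @return An object of class `nmm_posterior` with elements `eta`, `sd`,
#'   `Sigma`, `F`, `sigma2`, `n_iter`, `converged`, `natural` (natural-scale
#'   posterior values), `residual`, `priors`.
#' @export
em_gauss_newton <- function(y, forward, priors, opts = list()) {
  o <- utils::modifyList(
    list(max_iter = 64L, tol = 1e-4, fd_step = 1e-3, sigma2 = NULL,
         update_sigma2 = TRUE, sigma2_min = 1e-10, init = NULL,
         max_halvings = 8L, ridge = 1e-10), opts)
  act <- active_priors(priors)
  pn <- priors$name[act]
  p <- sum(act)
  N <- length(y)
  v0 <- priors$var[act]
  th <- rep(0, p)
  if (!is.null(o$init)) {
    if (!is.null(names(o$init))) th[match(names(o$init), pn)] <- o$init
    else { stopifnot(length(o$init) == p); th <- as.numeric(o$init) }
  }
  names(th) <- pn
  safe <- function(t_) tryCatch(forward(t_), error = function(e) NULL)
  h0 <- forward(th)
  if (length(h0) != N) stop("forward prediction and data lengths differ")
  r0 <- y - h0
  sigma2 <- if (!is.null(o$sigma2)) o$sigma2
  else max(mean(r0^2), o$sigma2_min)
  logjoint <- function(rr, th_, s2)
    -0.5 * sum(rr^2) / s2 - 0.5 * N * log(2 * pi * s2) -
      0.5 * sum(th_^2 / v0)
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < o$max_iter) {
    n_iter <- n_iter + 1L
    J <- fd_jacobian(forward, th, h0, o$fd_step)
    JtJ <- crossprod(J)
    if (o$update_sigma2) {
      Sg <- solve_spd(JtJ / sigma2 + diag(1 / v0, p), ridge = o$ridge)
      sigma2 <- max((sum(r0^2) + sum(JtJ * Sg)) / N, o$sigma2_min)
    }
    Hm <- JtJ / sigma2 + diag(1 / v0, p)
    g <- crossprod(J, r0) / sigma2 - th / v0
    dth <- as.numeric(solve_spd(Hm, g, ridge = o$ridge))
    lj0 <- logjoint(r0, th, sigma2)
    step <- 1
    accepted <- FALSE
    for (hh in 0:o$max_halvings) {
      thn <- th + step * dth
      hn <- safe(thn)
      if (!is.null(hn)) {
        rn <- y - hn
        if (logjoint(rn, thn, sigma2) >= lj0 - 1e-12) {
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- TRUE  # no admissible improving step: local optimum
      break
    }
    delta <- max(abs(thn - th))
    th <- thn; h0 <- hn; r0 <- rn
    if (delta < o$tol) {
      converged <- TRUE
      break
    }
  }
  J <- fd_jacobian(forward, th, h0, o$fd_step)
  Hm <- crossprod(J) / sigma2 + diag(1 / v0, p)
  Sigma <- solve_spd(Hm, ridge = o$ridge)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(pn, pn)
  Fe <- laplace_free_energy(r0, sigma2, th, v0, Sigma)
  if (!converged && o$max_iter > 0L)
    warning("EM Gauss-Newton did not converge within max_iter; ",
            "returning last iterate")
  structure(list(eta = th, sd = sqrt(diag(Sigma)), Sigma = Sigma, F = Fe,
                 sigma2 = sigma2, lambda = sigma2, n_iter = n_iter,
                 converged = converged, natural = to_natural(th, priors),
                 residual = r0, priors = priors),
            class = "nmm_posterior")
}

#' Free energy of a fitted posterior
#'
#' Recomputes the Laplace free energy from the components stored in an
#' [em_gauss_newton()] posterior.
#'
#' @param posterior An `nmm_posterior`.
#' @return The free energy (scalar, equal to `posterior$F`).
#' @export
free_energy <- function(posterior) {
  stopifnot(inherits(posterior, "nmm_posterior"))
  v0 <- posterior$priors$var[active_priors(posterior$priors)]
  laplace_free_energy(posterior$residual, posterior$sigma2, posterior$eta,
                      v0, posterior$Sigma)
}

#' Log Bayes factor between two models
#'
#' @param F_i,F_j Free energies (approximate log evidences) of models i
#'   and j, or `nmm_posterior` objects.
#' @return `ln B_ij = F_i - F_j`.
#' @export
log_bayes_factor <- function(F_i, F_j) {
  if (inherits(F_i, "nmm_posterior")) F_i <- F_i$F
  if (inherits(F_j, "nmm_posterior")) F_j <- F_j$F
  F_i - F_j
}

#' Strong-evidence decision on a log Bayes factor
#'
#' Conventional threshold: a log-evidence difference of three or more is
#' strong evidence for the first model.
#'
#' @param lnB Log Bayes factor.
#' @return Logical.
#' @export
is_strong_evidence <- function(lnB) lnB >= 3

#' Nonzero-connection decision for a shrinkage-prior connection
#'
#' A squared-reparameterized (uncertain) connection is declared nonzero
#' when the one-sided 10% tail of its latent posterior excludes zero, i.e.
#' `|eta| / sd > z_0.90` (about 1.2816).
#'
#' @param posterior An `nmm_posterior`.
#' @param name Name of an uncertain (`sq`-class) connection.
#' @return Logical.
#' @export
connection_nonzero <- function(posterior, name) {
  stopifnot(inherits(posterior, "nmm_posterior"))
  pr <- posterior$priors
  row <- match(name, pr$name)
  if (is.na(row)) stop("unknown parameter: ", name)
  if (pr$class[row] != "sq")
    stop(name, " does not carry a shrinkage (squared) prior")
  z <- abs(posterior$eta[[name]]) / posterior$sd[[name]]
  z > stats::qnorm(0.90)
}

#' @export
print.nmm_posterior <- function(x, ...) {
  cat(sprintf("<nmm_posterior: %d parameters, F = %.2f, sigma2 = %.3g, %d iterations%s>\n",
              length(x$eta), x$F, x$sigma2, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
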