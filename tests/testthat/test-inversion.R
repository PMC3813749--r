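test_that("re-parameterization maps latent to natural scale", {
  pr <- lccm_priors()
  act <- active_priors(pr)
  th <- setNames(rep(0, sum(act)), pr$name[act])
  phi <- to_natural(th, pr)
  expect_equal(phi[["C2"]], 108)       # exp class at theta = 0
  expect_equal(phi[["C6"]], 0)         # shrinkage class at theta = 0
  expect_equal(phi[["He"]], 3.25e-3)   # constant passed through
  th[["C8"]] <- 2
  expect_equal(to_natural(th, pr)[["C8"]], 4)
  th[["C8"]] <- -2                      # sign symmetry of the square
  expect_equal(to_natural(th, pr)[["C8"]], 4)
  th[["tau_C2"]] <- 0.5
  expect_equal(to_natural(th, pr)[["tau_C2"]], 0.01 * exp(0.5))
  expect_error(to_natural(th[-1], pr))
})

test_that("EM Gauss-Newton reproduces the conjugate Gaussian posterior", {
  set.seed(42)
  p <- 4; N <- 60
  A <- matrix(rnorm(N * p), N, p)
  pri <- data.frame(name = letters[1:p], class = "exp", u = 1,
                    var = c(0.5, 2, 1, 0.25), stringsAsFactors = FALSE)
  y <- as.numeric(A %*% c(0.3, -0.5, 1, 0.2)) + rnorm(N, 0, 0.1)
  s2 <- 0.01
  post <- em_gauss_newton(y, function(th) as.numeric(A %*% th), pri,
                          opts = list(sigma2 = s2, update_sigma2 = FALSE))
  Sig <- solve(crossprod(A) / s2 + diag(1 / pri$var))
  mu <- as.numeric(Sig %*% crossprod(A, y) / s2)
  expect_lt(max(abs(post$eta - mu)), 1e-8)
  expect_lt(max(abs(post$Sigma - Sig)), 1e-8)
  # free energy equals its closed Laplace form for the linear model
  expect_equal(free_energy(post), post$F)
})

test_that("zero iterations return the prior mean", {
  pri <- data.frame(name = c("a", "b"), class = "exp", u = 1, var = 0.5,
                    stringsAsFactors = FALSE)
  post <- em_gauss_newton(rnorm(10), function(th) rep(sum(th), 10), pri,
                          opts = list(max_iter = 0))
  expect_equal(unname(post$eta), c(0, 0))
})

test_that("free energy charges for superfluous parameters", {
  # identical residual and noise; the larger model holds an extra
  # parameter at a nonzero posterior mean
  r <- rnorm(50, 0, 0.1)
  s2 <- 0.01
  F_small <- laplace_free_energy(r, s2, eta = 0.2, prior_var = 0.5,
                                 Sigma = matrix(0.05))
  F_big <- laplace_free_energy(r, s2, eta = c(0.2, 0.8),
                               prior_var = c(0.5, 0.5),
                               Sigma = diag(c(0.05, 0.05)))
  expect_lt(F_big, F_small)
  # with no parameters F reduces to the Gaussian log-likelihood
  F0 <- laplace_free_energy(r, s2, eta = numeric(0),
                            prior_var = numeric(0),
                            Sigma = matrix(numeric(0), 0, 0))
  expect_equal(F0, sum(dnorm(r, 0, sqrt(s2), log = TRUE)))
})

test_that("Bayes-factor bookkeeping and the strong-evidence rule", {
  expect_equal(log_bayes_factor(10, 10), 0)
  expect_false(is_strong_evidence(0))
  expect_equal(log_bayes_factor(12, 7), -log_bayes_factor(7, 12))
  expect_true(is_strong_evidence(3.0))
  expect_false(is_strong_evidence(2.999))
})

test_that("nonzero-connection decision uses the one-sided 10% tail", {
  pri <- data.frame(name = c("C8", "C2"), class = c("sq", "exp"),
                    u = c(0, 108), var = c(1e4, 0.5),
                    stringsAsFactors = FALSE)
  fake <- structure(list(eta = c(C8 = 2, C2 = 0), sd = c(C8 = 1, C2 = 1),
                         priors = pri), class = "nmm_posterior")
  expect_true(connection_nonzero(fake, "C8"))
  fake$eta[["C8"]] <- 1.0
  expect_false(connection_nonzero(fake, "C8"))   # 1.0 < 1.2816
  fake$eta[["C8"]] <- 0
  expect_false(connection_nonzero(fake, "C8"))
  expect_error(connection_nonzero(fake, "C2"), "shrinkage")
  expect_error(connection_nonzero(fake, "zz"), "unknown")
})

test_that("predictor responds linearly to small latent perturbations", {
  pr <- jrm_priors()
  h <- nmm_predictor(build_jrm, pr, train = make_tone_train(2),
                     t_span = c(-0.1, 1))
  act <- sum(active_priors(pr))
  th0 <- rep(0, act)
  y0 <- h(th0)
  expect_equal(max(abs(y0)), 1, tolerance = 1e-12)  # unit-scaled at prior mean
  j <- which(pr$name[active_priors(pr)] == "C2j")
  d <- 1e-3
  thp <- th0; thp[j] <- d
  thm <- th0; thm[j] <- -d
  grad <- (h(thp) - h(thm)) / (2 * d)
  # first-order Taylor check at twice the step
  pred <- y0 + 2 * d * grad
  thpp <- th0; thpp[j] <- 2 * d
  expect_lt(max(abs(h(thpp) - pred)), 1e-4 * max(abs(y0)))
})
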