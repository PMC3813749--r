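test_that("sigmoid crosses the origin and matches its closed form", {
  p <- sigmoid_params()
  expect_identical(sigmoid(0, p), 0)
  # half-activation point: 2.5 - 5/(1 + exp(3.36))
  expect_equal(sigmoid(p$u0, p), 2.5 - 5 / (1 + exp(3.36)), tolerance = 1e-12)
  # supremum: 5 - 5/(1 + exp(3.36)) ~ 4.832
  expect_equal(sigmoid_max(p), 5 - 5 / (1 + exp(3.36)), tolerance = 1e-12)
  expect_equal(sigmoid(1, p), sigmoid_max(p), tolerance = 1e-9)
  expect_error(sigmoid(NaN, p), "non-finite")
})

test_that("sigmoid is strictly increasing and bounded", {
  set.seed(1)
  for (i in 1:20) {
    p <- sigmoid_params(e0 = runif(1, 0.5, 5), r = runif(1, 100, 1000),
                        u0 = runif(1, 1e-3, 2e-2))
    u <- sort(runif(2, -0.05, 0.05))
    expect_lt(sigmoid(u[1], p), sigmoid(u[2], p))
    expect_identical(sigmoid(0, p), 0)
    lo <- -2 * p$e0 / (1 + exp(p$r * p$u0))
    expect_gte(sigmoid(u[1], p), lo)
    expect_lt(sigmoid(u[2], p), sigmoid_max(p))
  }
})

test_that("sigmoid_max is the large-potential limit", {
  p <- sigmoid_params(e0 = 2.5, r = 2000, u0 = 0.05)  # r*u0 large
  expect_equal(sigmoid_max(p), 2 * p$e0, tolerance = 1e-12)
})

test_that("alpha kernel ODE reproduces the closed-form impulse response", {
  p <- alpha_kernel_params(H = 3.25e-3, tau = 10e-3)
  # unit Dirac input from rest: z jumps to H/tau, then free decay
  f <- function(t, s) {
    d <- kernel_rhs(list(y = s[1], z = s[2]), 0, p)
    c(d[["dy"]], d[["dz"]])
  }
  sol <- rk4_integrate(f, c(0, p$H / p$tau), 0, 10 * p$tau, 1e-3)
  ref <- kernel_impulse_response(sol$t, p)
  err <- max(abs(sol$y[, 1] - ref)) / max(ref)
  expect_lt(err, 1e-4)
  # peak at t = tau with value H/e
  expect_equal(kernel_impulse_response(p$tau, p), p$H / exp(1),
               tolerance = 1e-12)
  expect_equal(max(ref), p$H / exp(1), tolerance = 1e-4)
})

test_that("alpha kernel rest state and step-input steady state", {
  p <- alpha_kernel_params(H = 3.25e-3, tau = 10e-3)
  expect_equal(unname(kernel_rhs(synapse_state(0, 0), 0, p)), c(0, 0))
  # constant input Q: y(inf) = H * tau * Q
  Q <- 4
  f <- function(t, s) {
    d <- kernel_rhs(list(y = s[1], z = s[2]), Q, p)
    c(d[["dy"]], d[["dz"]])
  }
  sol <- rk4_integrate(f, c(0, 0), 0, 20 * p$tau, 1e-3)
  expect_equal(sol$y[nrow(sol$y), 1], p$H * p$tau * Q, tolerance = 1e-6)
})

test_that("impulse response is causal and vanishing", {
  p <- alpha_kernel_params()
  expect_identical(kernel_impulse_response(0, p), 0)
  expect_identical(kernel_impulse_response(-0.01, p), 0)
  expect_lt(kernel_impulse_response(100 * p$tau, p), 1e-30)
})
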