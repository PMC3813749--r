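test_that("laminar circuit has the expected state bookkeeping", {
  m <- build_lccm()
  expect_equal(n_core_states(m), 26)
  expect_equal(nrow(m$pools), 9)
  expect_equal(n_core_states(build_lccm(include_uncertain = character(0))), 14)
  for (nm in uncertain_connections()) {
    kept <- setdiff(uncertain_connections(), nm)
    expect_equal(n_core_states(build_lccm(include_uncertain = kept)), 24)
  }
  expect_error(build_lccm(include_uncertain = "C99"), "unknown")
  # inhibitory connections originate only from interneurons
  inh <- m$connections[m$connections$sign == "inh", ]
  expect_true(all(grepl("IIN", inh$source)))
})

test_that("Jansen-Rit baseline has 6 core states and shares the machinery", {
  mj <- build_jrm()
  expect_equal(n_core_states(mj), 6)
  expect_equal(nrow(mj$pools), 2)
  sim <- simulate_model(mj, NULL, c(0, 0.5))
  expect_true(all(sim$U == 0))
  expect_true(all(sim$A == 1))
})

test_that("rest is a fixed point of the full system", {
  for (m in list(build_lccm(), build_jrm())) {
    d <- model_rhs(m)  # rest state, no input
    expect_true(all(abs(c(d$dy, d$dz, d$dA)) == 0))
  }
  sim <- simulate_model(build_lccm(), NULL, c(0, 1))
  expect_true(all(sim$U == 0) && all(sim$Y == 0) && all(sim$A == 1))
})

test_that("compiled integrator agrees with the pure-R right-hand side", {
  m <- build_lccm()
  tr <- make_tone_train(2, 0.25)
  dt <- 1e-3
  J <- nrow(m$transforms); K <- nrow(m$pools)
  pack <- function(s) c(rbind(s$y, s$z), s$A)
  unpack <- function(v) list(y = v[seq(1, 2 * J, 2)], z = v[seq(2, 2 * J, 2)],
                             A = v[2 * J + seq_len(K)])
  f <- function(t, v) {
    d <- model_rhs(m, unpack(v), t, tr)
    c(rbind(d$dy, d$dz), d$dA)
  }
  sol <- rk4_integrate(f, c(rep(0, 2 * J), rep(1, K)), -0.1, 0.4, dt)
  sim <- simulate_model(m, tr, c(-0.1, 0.4), dt)
  uR <- t(vapply(seq_len(nrow(sol$y)),
                 function(i) model_rhs(m, unpack(sol$y[i, ]), sol$t[i], tr)$u,
                 numeric(5)))
  expect_lt(max(abs(uR - sim$U)), 1e-15)
  expect_lt(max(abs(sol$y[, 2 * J + seq_len(K)] - sim$A)), 1e-13)
})

test_that("zeroing a connection equals removing it from the graph", {
  params <- prior_expectations()
  th <- setNames(rep(0, sum(active_priors(lccm_priors()))),
                 lccm_priors()$name[active_priors(lccm_priors())])
  th[c("C6", "C8")] <- c(2, 3)  # phi = 4, 9
  phi <- to_natural(th, lccm_priors())
  tr <- make_tone_train(3)
  w_zero <- local({
    phi0 <- phi; phi0[c("C6", "C8")] <- 0
    observe(simulate_model(build_lccm(phi0), tr, c(-0.1, 1.5)))
  })
  w_excl <- observe(simulate_model(
    build_lccm(phi, include_uncertain = setdiff(uncertain_connections(),
                                                c("C6", "C8"))),
    tr, c(-0.1, 1.5)))
  expect_equal(w_zero$y, w_excl$y, tolerance = 1e-14)
  # and the full graph with those strengths differs
  w_full <- observe(simulate_model(build_lccm(phi), tr, c(-0.1, 1.5)))
  expect_gt(max(abs(w_full$y - w_zero$y)), 0)
})

test_that("halving the step leaves the waveform unchanged to 1e-6", {
  m <- build_lccm()
  tr <- make_tone_train(5)
  y1 <- observe(simulate_model(m, tr, c(-0.1, 2.5), 1e-3), fs = 125)$y
  y2 <- observe(simulate_model(m, tr, c(-0.1, 2.5), 5e-4), fs = 125)$y
  expect_lt(sqrt(mean((y1 - y2)^2)) / sqrt(mean(y1^2)), 1e-6)
})

test_that("observation sums pyramidal potentials at 125 Hz", {
  m <- build_lccm()
  tr <- make_tone_train(5)
  sim <- simulate_model(m, tr, c(-0.1, 2.5))
  wf <- observe(sim, fs = 125)
  expect_equal(wf$fs, 125)
  expect_length(wf$y, 326)
  expect_equal(wf$y[1], unname(sim$U[1, "sPC"] + sim$U[1, "dPC"]))
  wfn <- observe(sim, fs = 125, normalize = TRUE)
  expect_equal(max(abs(wfn$y)), 1)
  expect_error(observe(sim, fs = 300), "divide")
  # Jansen-Rit observation reads the single pyramidal mass
  simj <- simulate_model(build_jrm(), tr, c(-0.1, 2.5))
  expect_equal(observe(simj, fs = 1000)$y, unname(simj$U[, "PC"]))
})

test_that("repeated tones habituate the response and deplete the pools", {
  m <- build_lccm()
  tr <- make_tone_train(5)
  sim <- simulate_model(m, tr, c(-0.1, 2.5))
  expect_true(all(sim$A >= -1e-9 & sim$A <= 1 + 1e-9))
  expect_true(all(sim$A[sim$t <= 0, ] == 1))
  pk <- tone_peaks(observe(sim, fs = 1000), tr)
  expect_true(all(diff(pk) <= 0))
  drops <- -diff(pk)
  expect_equal(which.max(drops), 1L)
})
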