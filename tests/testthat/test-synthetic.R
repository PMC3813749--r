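test_that("datasets are reproducible bit-exactly from their seed", {
  d1 <- generate_dataset(noise_sd = 0.05, seed = 3)
  d2 <- generate_dataset(noise_sd = 0.05, seed = 3)
  expect_identical(d1$waveform$y, d2$waveform$y)
  d3 <- generate_dataset(noise_sd = 0.05, seed = 4)
  expect_false(identical(d1$waveform$y, d3$waveform$y))
})

test_that("noise-free data equal the forward prediction and rest before onset", {
  d <- generate_dataset(noise_sd = 0, seed = 1)
  expect_identical(d$waveform$y, d$clean$y)
  expect_true(all(d$clean$y[d$clean$t < 0] == 0))
  expect_equal(max(abs(d$clean$y)), 1)
  expect_equal(d$waveform$fs, 125)
})

test_that("added noise has the requested amplitude", {
  res <- unlist(lapply(1:20, function(s) {
    d <- generate_dataset(noise_sd = 0.05, seed = s)
    d$waveform$y - d$clean$y
  }))
  expect_equal(sd(res), 0.05, tolerance = 0.1)
})

test_that("prior draws are deterministic with the requested spread", {
  pr <- lccm_priors()
  expect_identical(draw_parameters(pr, seed = 5), draw_parameters(pr, seed = 5))
  expect_true(all(draw_parameters(pr, seed = 5, scale = 0) == 0))
  th <- vapply(1:1000, function(s) draw_parameters(pr, seed = s)[["C2"]],
               numeric(1))
  expect_equal(sd(th), sqrt(0.5), tolerance = 0.1)
})

test_that("suppression weakens with longer inter-stimulus intervals", {
  tab <- isi_experiment(c(0.5, 1.0, 1.5))
  expect_true(all(diff(tab$suppression) < 0))
  # no depression, no suppression
  params <- prior_expectations()
  params[grep("^nd_", names(params))] <- 0
  tab0 <- isi_experiment(c(0.5, 1.0), params = params)
  # residual "suppression" without depression reflects only the overlap of
  # successive linear response tails, orders of magnitude below habituation
  expect_lt(max(abs(tab0$suppression)), 1e-3)
  expect_error(isi_experiment(0.1), "0.2")
})

test_that("probe response approaches the first-tone response with silence", {
  pr <- probe_recovery(silences = c(1, 3, 6), n_tones = 5)
  expect_true(all(diff(pr$ratio) > 0))
  expect_gt(pr$ratio[3], 0.99)
  expect_true(all(pr$ratio <= 1 + 1e-9))
})

test_that("parameter-recovery harness reports bias, rmse and coverage", {
  # tiny deterministic run on the cheaper baseline model
  rep <- suppressWarnings(
    recovery_experiment(n_reps = 1, noise_sd = 0.02, seeds = 21,
                        scale = 0.1, model = "JRM",
                        opts = list(max_iter = 4)))
  expect_true(all(c("bias", "rmse", "coverage") %in% names(rep$summary)))
  expect_equal(nrow(rep$summary), sum(active_priors(jrm_priors())))
  expect_true(all(rep$summary$rmse >= 0))
})
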