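test_that("biexponential + IRF fit recovers noiseless parameters exactly", {
  t <- c(seq(-0.5, 1, by = 0.05), 10^seq(log10(1.2), log10(300), length.out = 25))
  sig <- 0.175 / (2 * sqrt(2 * log(2)))
  truth <- list(A1 = 0.07, A2 = 0.03, tau1 = 0.4, tau2 = 38)
  y <- truth$A1 * trixs:::.emg(t, truth$tau1, sig) +
    truth$A2 * trixs:::.emg(t, truth$tau2, sig)
  fit <- fit_gp_decay(t, y, irf_fwhm = 0.175)
  expect_equal(fit$tau1, truth$tau1, tolerance = 0.01)
  expect_equal(fit$tau2, truth$tau2, tolerance = 0.01)
  expect_equal(fit$A1, truth$A1, tolerance = 0.01)
  expect_equal(fit$A2, truth$A2, tolerance = 0.01)
  expect_equal(fit$a1_frac, 0.7, tolerance = 0.01)
  expect_lt(max(abs(fit$residuals)), 1e-8 * max(y))
  expect_false(fit$single_exponential)
  expect_equal(tidy(fit)$estimate[1:2], c(fit$tau1, fit$tau2))
})

test_that("a vanishing second component collapses to a flagged single exponential", {
  t <- c(seq(-0.3, 1, by = 0.05), 2, 5, 10, 30)
  sig <- trixs:::.irf_sigma(0.175)
  y <- 0.1 * trixs:::.emg(t, 0.5, sig)
  fit <- fit_gp_decay(t, y, irf_fwhm = 0.175)
  expect_true(fit$single_exponential)
  expect_equal(fit$tau1, 0.5, tolerance = 0.01)
  expect_true(is.na(fit$tau2))
})

test_that("biexponential fit tolerates noise on log-spaced sampling", {
  t <- 10^seq(log10(0.05), log10(300), length.out = 30)
  sig <- trixs:::.irf_sigma(0.175)
  y0 <- 0.07 * trixs:::.emg(t, 0.4, sig) + 0.03 * trixs:::.emg(t, 38, sig)
  # Monte-Carlo over independent draws of 5% proportional noise: the
  # typical tau2 error stays within 15%
  errs <- vapply(1:5, function(sd_seed) {
    withr::with_seed(sd_seed, y <- y0 * (1 + rnorm(length(t), sd = 0.05)))
    fit <- fit_gp_decay(t, y, irf_fwhm = 0.175)
    abs(fit$tau2 - 38) / 38
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("cage-escape probability follows its ratio definition", {
  t <- seq(0, 3, by = 0.1)
  expect_equal(cage_escape_probability(t, rep(0.1, length(t)),
                                       rep(0.38, length(t))), 0.38)
  expect_equal(cage_escape_probability(t, rep(0.1, length(t)),
                                       rep(0, length(t))), 0)
  expect_equal(cage_escape_probability(t, rep(0.2, length(t)),
                                       rep(1, length(t))), 1)
  # invariant under a common rescaling of the amplitudes
  a_iso <- 0.1 * exp(-t / 5); a_ng <- 0.4 * (1 - exp(-t))
  p1 <- cage_escape_probability(t, a_iso, a_ng)
  p2 <- cage_escape_probability(t, 7 * a_iso, a_ng)
  expect_equal(p1, p2)
  expect_error(cage_escape_probability(c(0, 0.5), c(1, 1), c(1, 1)), "window")
})

test_that("dissociation and angular speeds recover linear ballistic motion", {
  t <- c(-0.1, seq(0, 0.4, by = 0.05), seq(0.6, 2, by = 0.2))
  r23 <- ifelse(t <= 0, 3.1, ifelse(t <= 0.4, 3.1 + 6 * t, 3.1 + 6 * 0.4))
  v <- dissociation_speed(t, r23)
  expect_equal(v$v_d, 6.0, tolerance = 1e-10)
  expect_equal(v$travel, 2.4, tolerance = 1e-10)
  flat <- dissociation_speed(t, rep(3.1, length(t)))
  expect_equal(flat$v_d, 0)
  expect_equal(flat$travel, 0)

  alpha <- ifelse(t <= 0, pi, pmax(pi - 4 * pmin(t, 0.4), 0))
  expect_equal(angular_speed(t, alpha)$omega, 4, tolerance = 1e-10)
  expect_equal(angular_speed(t, rep(2, length(t)))$omega, 0)

  withr::with_seed(5, {
    # ballistic rise arrested at a sampled timepoint (t = 0.4), followed by
    # the cage-relaxation decline of the reaction scheme
    r_clean <- ifelse(t <= 0, 3.1,
                      ifelse(t <= 0.4, 3.1 + 4.8 * t,
                             3.1 + 4.8 * 0.4 - 0.5 * (t - 0.4)))
    r_noisy <- r_clean + rnorm(length(t), sd = 0.05)
    expect_equal(dissociation_speed(t, r_noisy)$v_d, 4.8, tolerance = 0.1)
  })
})

test_that("excluded timepoints are dropped from the ballistic fit", {
  t <- c(0, 0.1, 0.2, 0.3, 0.4, 0.6, 1)
  r23 <- c(3.1, 3.7, 9.9, 4.9, 5.5, 5.5, 5.5) # corrupted point at t = 0.2
  with_out <- dissociation_speed(t, r23, exclude = 0.2)
  expect_equal(with_out$v_d, 6.0, tolerance = 0.05)
})

test_that("energy partitioning reproduces the published translational energies", {
  speeds <- c(acetonitrile = 6.0, water = 4.8, ethanol = 4.4, methanol = 4.0)
  printed <- c(acetonitrile = 15.2, water = 9.8, ethanol = 8.2, methanol = 6.8)
  for (sv in names(speeds)) {
    e <- energy_partitioning(speeds[[sv]], 0)$E_trans
    expect_lt(abs(e - printed[[sv]]), 0.1)
  }
  # rotational energy with the I2- own-centre inertia convention
  expect_equal(energy_partitioning(0, 4, r12 = 3.1)$E_rot, 48.8, tolerance = 0.01)
})

test_that("molar photon energy at 400 nm rounds to 300 kJ/mol", {
  expect_equal(signif(photon_energy(400), 2), 300)
  expect_equal(photon_energy(400), 299.07, tolerance = 1e-3)
})

test_that("IRF width is recovered from an error-function rise", {
  t <- seq(-0.5, 0.45, by = 0.02)
  sig <- trixs:::.irf_sigma(0.175)
  y <- 5 + 40 * pnorm(t / sig)
  fit <- irf_estimate(t, y)
  expect_equal(fit$fwhm, 0.175, tolerance = 0.01)
  expect_equal(fit$t0, 0, tolerance = 0.01)
  withr::with_seed(9, {
    yn <- y + rnorm(length(t), sd = 0.8)
    expect_equal(irf_estimate(t, yn)$fwhm, 0.175, tolerance = 0.1 * 0.175)
  })
  # an unresolved (sub-bin) step is flagged
  y_step <- 5 + 40 * (t >= 0.013)
  fit_step <- irf_estimate(t, y_step)
  expect_true(fit_step$below_resolution)
  expect_error(irf_estimate(t, rep(1, length(t))), "No signal rise")
})
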