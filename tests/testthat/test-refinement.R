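test_that("chi-square has its closed forms and matches an independent sum", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0)
  k <- 8
  x <- truth_x(tiny_truth(), k)
  dt <- trixs:::.data_at(ds, k)
  expect_equal(chi2(x, dt, ctx), 0)

  # constant residual 1 with sigma = 1 over N0 + N2 points
  m0 <- model_iso(x, ctx)$dS0
  m2 <- model_aniso(x, ctx)$dS2
  n <- length(ctx$q)
  dt1 <- list(dS0 = m0 + 1, dS2 = m2 + 1, err0 = rep(1, n), err2 = rep(1, n))
  expect_equal(chi2(x, dt1, ctx), 2 * n)

  withr::with_seed(3, {
    r0 <- rnorm(n); r2 <- rnorm(n); s0 <- runif(n, 0.5, 2); s2 <- runif(n, 0.5, 2)
    dt2 <- list(dS0 = m0 + r0, dS2 = m2 + r2, err0 = s0, err2 = s2)
    expect_equal(chi2(x, dt2, ctx), sum((r0 / s0)^2) + sum((r2 / s2)^2),
                 tolerance = 1e-10)
  })
  dt_bad <- dt1; dt_bad$err0[3] <- 0
  expect_error(chi2(x, dt_bad, ctx), "positive")
})

test_that("regularization penalty is quadratic with per-parameter weights", {
  x <- truth_x(tiny_truth(), 8)
  expect_equal(regularization_penalty(x, x, lambda = 5), 0)
  expect_equal(regularization_penalty(x, x + 1, lambda = 0), 0)
  xp <- x
  xp["r23"] <- x[["r23"]] + 1
  xp["A_GP"] <- x[["A_GP"]] - 1
  expect_equal(regularization_penalty(x, xp, lambda = 3), 6)
  w <- refinement_config()$weights
  w["r23"] <- 4
  expect_equal(regularization_penalty(x, xp, lambda = 3, weights = w), 15)
})

test_that("noiseless single-timepoint refinement recovers the generating state", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0)
  k <- 8
  x <- truth_x(tiny_truth(), k)
  cfg <- refinement_config(lambda = 0, restarts = 4, seed = 7)
  res <- refine_timepoint(trixs:::.data_at(ds, k), NULL, ctx, cfg)
  expect_lt(abs(res$x[["r12"]] - x[["r12"]]), 0.02)
  expect_lt(abs(res$x[["r23"]] - x[["r23"]]), 0.02)
  expect_lt(abs(res$x[["alpha"]] - x[["alpha"]]), 0.02)
  for (nm in c("A_iso", "A_GP", "A_heat", "A_ani")) {
    expect_lt(abs(res$x[[nm]] - x[[nm]]), 0.01)
  }
  expect_true(res$converged)
  # the returned objective is the best across restarts
  expect_lte(res$objective, min(res$restarts$objective) + 1e-12)
})

test_that("more restarts can only improve the objective", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0.02, seed = 2)
  k <- 6
  dt <- trixs:::.data_at(ds, k)
  r1 <- refine_timepoint(dt, NULL, ctx,
                         refinement_config(lambda = 0, restarts = 1, seed = 42))
  r6 <- refine_timepoint(dt, NULL, ctx,
                         refinement_config(lambda = 0, restarts = 6, seed = 42))
  expect_lte(r6$objective, r1$objective + 1e-9)
})

test_that("pure heating data is identified as heating, not structure", {
  ctx <- tiny_ctx()
  n <- length(ctx$q)
  dt <- list(dS0 = 2.0 * ctx$heating, dS2 = rep(0, n),
             err0 = rep(1, n), err2 = rep(1, n))
  res <- refine_timepoint(dt, NULL, ctx,
                          refinement_config(lambda = 0, restarts = 6, seed = 3))
  expect_lt(res$x[["A_iso"]] * abs(1 - res$x[["A_GP"]]), 0.02)
  expect_equal(res$x[["A_heat"]], 2.0, tolerance = 0.02)
})

test_that("series refinement with lambda = 0 equals independent refinements", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0.02, seed = 2)
  sub <- structure(list(q = ds$q, t = ds$t[1:4], dS0 = ds$dS0[, 1:4],
                        dS2 = ds$dS2[, 1:4], err0 = ds$err0[, 1:4],
                        err2 = ds$err2[, 1:4], solvent = ds$solvent,
                        truth = NULL), class = "aniso_dataset")
  cfg <- refinement_config(lambda = 0, restarts = 2, seed = 17)
  ref <- refine_series(sub, ctx, cfg)
  for (step in 1:4) {
    ind <- refine_timepoint(trixs:::.data_at(sub, step), NULL, ctx, cfg,
                            seed = cfg$seed + step)
    got <- as.numeric(ref$params[step, trixs:::.param_names])
    expect_equal(got, unname(ind$x[trixs:::.param_names]), tolerance = 1e-10)
  }
})

test_that("stronger regularization smooths the recovered trajectory", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0.05, seed = 8)
  cfg0 <- refinement_config(lambda = 0, restarts = 2, seed = 9)
  cfgL <- refinement_config(lambda = 1e4, restarts = 2, seed = 9)
  tv <- function(x) sum(abs(diff(x)))
  r0 <- refine_series(ds, ctx, cfg0)
  rL <- refine_series(ds, ctx, cfgL)
  expect_lte(tv(rL$params$r23), tv(r0$params$r23))
})

test_that("tidy and glance summarize a refinement", {
  ref <- tiny_refinement()
  td <- tidy(ref)
  expect_true(all(c("t", "parameter", "value") %in% names(td)))
  expect_equal(nrow(td), nrow(ref$params) * 8)
  gl <- glance(ref)
  expect_equal(gl$n_timepoints, nrow(ref$params))
  expect_gte(gl$total_chi2, 0)
})

test_that("sensitivity intervals match the quadratic closed form on A_heat", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0)
  k <- 8
  x <- truth_x(tiny_truth(), k)
  dt <- trixs:::.data_at(ds, k)
  ci <- parameter_uncertainty(x, dt, ctx, refinement_config(lambda = 0))
  # chi2 is exactly quadratic in A_heat: delta = 1/sqrt(sum((h/sigma)^2))
  half_width <- 1 / sqrt(sum((ctx$heating / dt$err0)^2))
  row <- ci[ci$parameter == "A_heat", ]
  expect_equal(row$upper - row$estimate, half_width, tolerance = 1e-4)
  expect_equal(row$estimate - row$lower, half_width, tolerance = 1e-4)
  expect_false(row$flat_lower || row$flat_upper)
})

test_that("sensitivity intervals scale with the noise level and flag flat directions", {
  ctx <- tiny_ctx()
  ds <- tiny_dataset(noise = 0)
  k <- 8
  x <- truth_x(tiny_truth(), k)
  dt1 <- trixs:::.data_at(ds, k)
  dt2 <- dt1
  dt2$err0 <- 2 * dt1$err0; dt2$err2 <- 2 * dt1$err2
  cfg <- refinement_config(lambda = 0)
  w1 <- parameter_uncertainty(x, dt1, ctx, cfg)
  w2 <- parameter_uncertainty(x, dt2, ctx, cfg)
  r23w <- function(ci) {
    r <- ci[ci$parameter == "r23", ]
    r$upper - r$lower
  }
  expect_equal(r23w(w2) / r23w(w1), 2, tolerance = 0.05)

  # amplitude of an absent species: A_iso = A_ani = 0 makes A_GP flat
  x0 <- x
  x0["A_iso"] <- 0
  x0["A_ani"] <- 0
  n <- length(ctx$q)
  dt0 <- list(dS0 = trixs:::.model_iso_curve(x0, ctx), dS2 = rep(0, n),
              err0 = rep(1, n), err2 = rep(1, n))
  ci0 <- parameter_uncertainty(x0, dt0, ctx, cfg)
  rgp <- ci0[ci0$parameter == "A_GP", ]
  expect_true(rgp$flat_lower && rgp$flat_upper)
})
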