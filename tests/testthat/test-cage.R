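test_that("synthetic RDFs have an excluded core, a placed peak, and a bulk limit", {
  sv <- solvent_spec("acetonitrile")
  g <- sv$gs_geometry
  rd <- synth_rdf(g, sv, r = seq(0, 12, by = 0.02),
                  shell = shell_params(r_peak = 3.5))
  heavy <- setdiff(dimnames(rd$g)[[2]], "H")
  for (v in heavy) {
    expect_true(all(rd$g[, v, rd$r < 2.6] == 0))
    expect_equal(unname(rd$g["I3", v, length(rd$r)]), 1, tolerance = 1e-3)
  }
  expect_equal(first_shell_radius(rd$r, rd$g["I3", "C", ]), 3.5,
               tolerance = 0.01)
  expect_error(shell_params(width = -0.1), "positive")
})

test_that("cross term vanishes for unstructured solvent and is linear in density", {
  sv <- solvent_spec("water")
  r <- seq(0, 12, by = 0.02)
  flat <- array(1, dim = c(3, 2, length(r)),
                dimnames = list(c("I1", "I2", "I3"), c("O", "H"), NULL))
  rdfs <- structure(list(r = r, g = flat, solvent = "water",
                         shell = shell_params()), class = "rdf_set")
  q <- seq(0.5, 4.5, by = 0.5)
  expect_equal(cage_cross_term(rdfs, sv, q)$S_cross, rep(0, length(q)))

  rdfs$g[3, "O", ] <- 1 + 0.8 * exp(-(r - 3.5)^2 / (2 * 0.4^2))
  sv2 <- sv
  sv2$densities <- 2 * sv$densities
  s1 <- cage_cross_term(rdfs, sv, q)$S_cross
  s2 <- cage_cross_term(rdfs, sv2, q)$S_cross
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("cross term matches a fine-grid quadrature oracle on a Gaussian-peak RDF", {
  sv <- solvent_spec("water")
  r <- seq(0, 30, by = 0.002)
  gm1 <- function(rr) 0.8 * exp(-(rr - 3.5)^2 / (2 * 0.4^2))
  arr <- array(1, dim = c(3, 2, length(r)),
               dimnames = list(c("I1", "I2", "I3"), c("O", "H"), NULL))
  arr[1, "O", ] <- 1 + gm1(r)
  rdfs <- structure(list(r = r, g = arr, solvent = "water",
                         shell = shell_params()), class = "rdf_set")
  q <- c(0.5, 1.0, 3.0, 4.5)
  got <- cage_cross_term(rdfs, sv, q)$S_cross
  want <- cross_term_oracle(gm1, q, sv$densities[["O"]], "O")
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("cross term decays towards high q and warns on unconverged RDFs", {
  sv <- solvent_spec("water")
  rd <- synth_rdf(sv$gs_geometry, sv, r = seq(0, 12, by = 0.02))
  q <- seq(0.05, 4.5, by = 0.05)
  s <- cage_cross_term(rd, sv, q)$S_cross
  expect_lt(abs(s[length(s)]), abs(s[1]))
  bad <- rd
  bad$r <- seq(0, 4, by = 0.02) # truncated inside the first shell
  bad$g <- rd$g[, , seq_along(bad$r)]
  expect_warning(cage_cross_term(bad, sv, q), "not converged")
})

test_that("displaced-volume term has its closed form and zero cases", {
  sv <- solvent_spec("acetonitrile")
  g <- sv$gs_geometry
  q <- seq(0.5, 4.5, by = 0.25)
  expect_equal(displaced_volume_term(g, sv, q, r_excl = 0)$S_dv,
               rep(0, length(q)))
  expect_error(displaced_volume_term(g, sv, q, r_excl = -1), ">= 0")
  # dummy-only intensity equals the closed-form Gaussian-sphere Debye sum
  got <- displaced_volume_term(g, sv, q, r_excl = 1.98,
                               include_solute_cross = FALSE)$S_dv
  V <- 4 / 3 * pi * 1.98^3
  fdv <- sv$rho_e * V * exp(-q^2 * V^(2 / 3) / (4 * pi))
  d <- pair_distances(g)
  sc <- function(x) ifelse(x < 1e-12, 1, sin(x) / x)
  want <- fdv^2 * (3 + 2 * (sc(q * d["I1", "I2"]) + sc(q * d["I2", "I3"]) +
                              sc(q * d["I1", "I3"])))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("trilinear interpolation is exact at nodes, on linear fields, and continuous", {
  lib <- tiny_library()
  gr <- lib$grid
  # node exactness
  g_node <- solute_geometry(gr$r12[2], gr$r23[3], gr$alpha[2])
  got <- interpolate_cage(g_node, lib)$S_cross
  expect_equal(max(abs(got - lib$cross[2, 3, 2, ])), 0, tolerance = 1e-12)
  # a synthetic library whose curves are linear in the coordinates is
  # reproduced exactly anywhere, and matches the independent weight oracle
  lin <- lib
  for (i1 in seq_along(gr$r12)) for (i2 in seq_along(gr$r23)) {
    for (i3 in seq_along(gr$alpha)) {
      lin$cross[i1, i2, i3, ] <- 2 * gr$r12[i1] - 3 * gr$r23[i2] +
        0.5 * gr$alpha[i3] + seq_along(lib$q) * 0
    }
  }
  withr::with_seed(21, {
    for (rep in 1:5) {
      p <- c(runif(1, min(gr$r12), max(gr$r12)),
             runif(1, min(gr$r23), max(gr$r23)),
             runif(1, min(gr$alpha), max(gr$alpha)))
      got <- interpolate_cage(solute_geometry(p[1], p[2], p[3]), lin)$S_cross
      expect_equal(got, rep(2 * p[1] - 3 * p[2] + 0.5 * p[3], length(lib$q)),
                   tolerance = 1e-10)
      got2 <- interpolate_cage(solute_geometry(p[1], p[2], p[3]), lib)$S_cross
      want2 <- trilinear_oracle(p[1], p[2], p[3], gr$r12, gr$r23, gr$alpha,
                                lib$cross)
      expect_equal(got2, want2, tolerance = 1e-12)
    }
  })
  # continuity across an interior cell face
  eps <- 1e-8
  f_lo <- interpolate_cage(solute_geometry(gr$r12[3] - eps, 5.0, 2.0), lib)$S_cross
  f_hi <- interpolate_cage(solute_geometry(gr$r12[3] + eps, 5.0, 2.0), lib)$S_cross
  expect_lt(max(abs(f_hi - f_lo)), 1e-6 * (1 + max(abs(f_lo))))
})

test_that("out-of-hull geometries clamp to the edge with a warning", {
  lib <- tiny_library()
  g_out <- solute_geometry(3.0, 100, pi)
  expect_warning(v1 <- interpolate_cage(g_out, lib)$S_cross, "clamped")
  g_edge <- solute_geometry(3.0, max(lib$grid$r23), pi)
  v2 <- interpolate_cage(g_edge, lib)$S_cross
  expect_equal(v1, v2)
})

test_that("cage difference is antisymmetric and zero for identical geometries", {
  lib <- tiny_library()
  sv <- solvent_spec("acetonitrile")
  g1 <- sv$gs_geometry
  g2 <- solute_geometry(3.1, 5.2, 2.3)
  expect_equal(cage_difference(g1, g1, lib, sv)$dS_cage,
               rep(0, length(lib$q)))
  expect_equal(cage_difference(g2, g1, lib, sv)$dS_cage,
               -cage_difference(g1, g2, lib, sv)$dS_cage)
})

test_that("library build is deterministic and reports its node count", {
  grid <- cage_grid(r12 = seq(2.8, 3.4, 0.3), r23 = seq(3, 6, 1.5),
                    alpha = seq(1, 3, 1))
  expect_equal(n_nodes(grid), 3 * 3 * 3)
  sv <- solvent_spec("methanol")
  q <- seq(0.5, 2.5, by = 0.5)
  l1 <- build_rdf_library(grid, sv, q, r = seq(0, 10, 0.05),
                          shell = shell_params(coupling = 0.3))
  l2 <- build_rdf_library(grid, sv, q, r = seq(0, 10, 0.05),
                          shell = shell_params(coupling = 0.3))
  expect_identical(l1$cross, l2$cross)
  expect_error(cage_grid(r12 = c(3, 2.8, 3.4)), "increasing")
  expect_error(cage_grid(r12 = c(2.6, 2.8, 3.3)), "uniform")
})

test_that("first-shell radius detects the first peak, also under noise", {
  r <- seq(0, 12, by = 0.04)
  g2 <- 1 + 0.8 * exp(-(r - 3.5)^2 / 0.32) + 0.4 * exp(-(r - 6.0)^2 / 0.5)
  expect_equal(first_shell_radius(r, g2), 3.5, tolerance = 0.02)
  withr::with_seed(33, {
    gn <- g2 + rnorm(length(r), sd = 0.03)
    expect_equal(first_shell_radius(r, gn, smooth = 7), 3.5, tolerance = 0.02)
  })
  expect_error(first_shell_radius(r, rep(1, length(r))), "No solvation-shell peak")
})
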