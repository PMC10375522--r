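#' Per-timepoint refinable parameter vector
#'
#' The state refined at each time delay: the geminate-pair geometry
#' (`r12`, `r23`, `alpha`), the excitation fraction `A_iso`, the
#' geminate fraction `A_GP` (the solvent-separated fraction is
#' `A_NG = 1 - A_GP`), the solvent-heating amplitude `A_heat` and the
#' anisotropy amplitude `A_ani` (which absorbs the photoselection
#' prefactor c2 and rotational dephasing).
#'
#' @param r12,r23,alpha Geminate-pair geometry (Angstrom, Angstrom, rad).
#' @param A_iso Excitation fraction, `>= 0`.
#' @param A_GP Geminate fraction in `[0, 1]`.
#' @param A_heat Heating amplitude (units of the heating reference curve).
#' @param A_ani Anisotropy amplitude (dimensionless).
#' @return Named numeric vector of class `param_vector`.
#' @export
param_vector <- function(r12, r23, alpha, A_iso, A_GP, A_heat, A_ani) {
  if (!is.finite(A_iso) || A_iso < 0) rlang::abort("`A_iso` must be >= 0.")
  if (!is.finite(A_GP) || A_GP < 0 || A_GP > 1) rlang::abort("`A_GP` must be in [0, 1].")
  solute_geometry(r12, r23, alpha) # validates the geometry fields
  structure(c(r12 = r12, r23 = r23, alpha = alpha, A_iso = A_iso,
              A_GP = A_GP, A_heat = A_heat, A_ani = A_ani),
            class = "param_vector")
}

.param_names <- c("r12", "r23", "alpha", "A_iso", "A_GP", "A_heat", "A_ani")

#' Forward-model context
#'
#' Precomputes everything fixed across refinement evaluations: the
#' ground-state solute curve, ground-state cage terms, the heating
#' reference and form factors, for a given solvent, q grid and cage
#' library. The solvent-separated (NG) species uses the convention
#' r23 = `ng_r23` (default 100 Angstrom), alpha = pi, and shares the
#' refined r12 of the geminate pair.
#'
#' @param solvent A [solvent_spec()].
#' @param q Strictly increasing q grid (1/Angstrom).
#' @param library An [build_rdf_library()] result on the same q grid.
#' @param sigma Debye-Waller rmsd values, see [dw_params()].
#' @param heating Heating reference curve on `q` (numeric vector); default
#'   the synthetic reference for the solvent.
#' @param ng_r23 Interfragment distance of the NG species (Angstrom).
#' @param r_excl Displaced-volume sphere radius (Angstrom).
#' @param dipole Transition-dipole convention passed to [dipole_axis()].
#' @return An object of class `forward_context`.
#' @export
forward_context <- function(solvent, q, library, sigma = dw_params(),
                            heating = NULL, ng_r23 = 100, r_excl = 1.98,
                            dipole = "long_axis") {
  stopifnot(inherits(solvent, "solvent_spec"), inherits(library, "rdf_library"))
  .check_qgrid(q)
  if (!isTRUE(all.equal(q, library$q))) {
    rlang::abort("`q` must match the cage library's q grid.")
  }
  if (is.null(heating)) {
    heating <- simulate_heating_reference(solvent, q)$dS_heat
  }
  if (length(heating) != length(q) || any(!is.finite(heating))) {
    rlang::abort("Heating reference must be a finite curve on the model q grid.")
  }
  gs <- solvent$gs_geometry
  sigma <- dw_params(sigma)
  FI <- .ff_matrix(q, sigma, c("I", "I", "I"))
  V <- 4 / 3 * pi * r_excl^3
  fdv <- if (r_excl > 0) solvent$rho_e * V * exp(-q^2 * V^(2 / 3) / (4 * pi)) else numeric(length(q))
  ctx <- list(
    solvent = solvent, q = q, library = library, sigma = sigma,
    heating = heating, ng_r23 = ng_r23, r_excl = r_excl, dipole = dipole,
    gs = gs,
    # evaluation caches
    FI = FI, Fself = colSums(FI^2), Fsum = colSums(FI),
    P12 = 2 * FI[1, ] * FI[2, ], P23 = 2 * FI[2, ] * FI[3, ],
    P13 = 2 * FI[1, ] * FI[3, ], fdv = fdv,
    gs_solute = .debye_curve(gs, q, sigma),
    gs_cross = .interp_cross(gs$r12, gs$r23, gs$alpha, library, warn = FALSE),
    gs_dv = .dv_curve(gs, solvent, q, r_excl, TRUE, sigma)
  )
  structure(ctx, class = "forward_context")
}

# --- fast evaluation path ----------------------------------------------------
# These internal routines evaluate the same expressions as the exported
# curve functions but reuse the form-factor and dummy-sphere caches in the
# context; the test suite asserts their equivalence to the public path.

# Full isotropic difference curve of one species at (r12, r23, alpha):
# solute difference + cage cross difference + displaced-volume difference.
.species_iso_fast <- function(r12, r23, alpha, ctx) {
  q <- ctx$q
  d13 <- sqrt(max(r12^2 + r23^2 - 2 * r12 * r23 * cos(alpha), 1e-12))
  s12 <- .sinc(q * r12); s23 <- .sinc(q * r23); s13 <- .sinc(q * d13)
  solute <- ctx$Fself + ctx$P12 * s12 + ctx$P23 * s23 + ctx$P13 * s13
  cross <- .interp_cross(r12, r23, alpha, ctx$library, warn = FALSE)
  f <- ctx$fdv
  FIs <- ctx$FI
  pairsum <- s12 + s23 + s13
  dv <- f^2 * (3 + 2 * pairsum) -
    2 * f * (ctx$Fsum + (FIs[1, ] + FIs[2, ]) * s12 +
               (FIs[2, ] + FIs[3, ]) * s23 + (FIs[1, ] + FIs[3, ]) * s13)
  (solute - ctx$gs_solute) + (cross - ctx$gs_cross) + (dv - ctx$gs_dv)
}

# Anisotropic (P2) curve of one species; dipole along the I1 -> I3 axis
# resolved from the same planar coordinates as solute_coords().
.species_aniso_fast <- function(r12, r23, alpha, ctx) {
  q <- ctx$q
  xyz <- rbind(c(-r12, 0, 0), c(0, 0, 0), r23 * c(-cos(alpha), sin(alpha), 0))
  dip <- if (identical(ctx$dipole, "long_axis")) {
    v <- xyz[3, ] - xyz[1, ]
    v / sqrt(sum(v^2))
  } else {
    dipole_axis(solute_geometry(r12, r23, alpha), ctx$dipole)
  }
  S2 <- numeric(length(q))
  pr <- list(c(1, 2, 1), c(2, 3, 2), c(1, 3, 3))
  Pmat <- rbind(ctx$P12, ctx$P23, ctx$P13)
  for (k in 1:3) {
    i <- pr[[k]][1]; j <- pr[[k]][2]
    v <- xyz[i, ] - xyz[j, ]
    d <- sqrt(sum(v^2))
    cz <- sum(v * dip) / d
    S2 <- S2 + Pmat[k, ] * (0.5 * (3 * cz^2 - 1)) * .sph_j2(q * d)
  }
  S2
}

.model_iso_curve <- function(x, ctx) {
  a <- min(max(x[["alpha"]], 0.01), pi)
  x[["A_iso"]] * (x[["A_GP"]] * .species_iso_fast(x[["r12"]], x[["r23"]], a, ctx) +
                    (1 - x[["A_GP"]]) * .species_iso_fast(x[["r12"]], ctx$ng_r23, pi, ctx)) +
    x[["A_heat"]] * ctx$heating
}

.model_aniso_curve <- function(x, ctx) {
  a <- min(max(x[["alpha"]], 0.01), pi)
  x[["A_ani"]] * (x[["A_GP"]] * .species_aniso_fast(x[["r12"]], x[["r23"]], a, ctx) +
                    (1 - x[["A_GP"]]) * .species_aniso_fast(x[["r12"]], ctx$ng_r23, pi, ctx))
}

#' Modeled isotropic difference scattering
#'
#' Composite isotropic model:
#' `dS0 = A_iso * [A_GP * dS0_GP + (1 - A_GP) * dS0_NG] + A_heat * dS_heat`,
#' where each species term is its solute difference plus its cage
#' (cross + displaced volume) difference relative to the ground state.
#'
#' @param x A [param_vector()] (or named vector with the same fields).
#' @param ctx A [forward_context()].
#' @return A tibble with columns `q` and `dS0`.
#' @export
model_iso <- function(x, ctx) {
  stopifnot(inherits(ctx, "forward_context"))
  tibble::tibble(q = ctx$q, dS0 = .model_iso_curve(x, ctx))
}

#' Modeled anisotropic difference scattering
#'
#' `dS2 = A_ani * [A_GP * S2_GP + (1 - A_GP) * S2_NG]`: solute-only, since
#' the isotropically oriented ground state carries no S2 and bulk-solvent
#' anisotropy is excluded from the model. The interfragment terms of the
#' NG species at r23 = 100 Angstrom are retained but numerically
#' negligible (j2 decay).
#'
#' @inheritParams model_iso
#' @return A tibble with columns `q` and `dS2`.
#' @export
model_aniso <- function(x, ctx) {
  stopifnot(inherits(ctx, "forward_context"))
  tibble::tibble(q = ctx$q, dS2 = .model_aniso_curve(x, ctx))
}
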