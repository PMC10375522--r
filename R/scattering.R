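# sinc(x) = sin(x)/x and the spherical Bessel function j2(x), with series
# limits below a small-argument threshold to avoid cancellation at x -> 0.
.sinc <- function(x) {
  out <- x
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 6 + x[small]^4 / 120
  xl <- x[!small]
  out[!small] <- sin(xl) / xl
  out
}

.sph_j2 <- function(x) {
  out <- x
  small <- abs(x) < 5e-2
  xs <- x[small]
  out[small] <- xs^2 / 15 * (1 - xs^2 / 14 + xs^4 / 504)
  xl <- x[!small]
  out[!small] <- (3 / xl^3 - 1 / xl) * sin(xl) - 3 * cos(xl) / xl^2
  out
}

# Damped form-factor matrix for a set of sites: rows = sites, cols = q.
.ff_matrix <- function(q, sigma, elements) {
  f <- vapply(seq_along(sigma), function(i) {
    atomic_form_factor(q, elements[i]) * exp(-q^2 * sigma[i]^2 / 2)
  }, numeric(length(q)))
  t(f) # n_sites x n_q
}

# Plain Debye double sum over arbitrary sites given a form-factor matrix
# (n x nq) and coordinates (n x 3). Self-terms have sinc = 1.
.debye_sum <- function(q, F, xyz) {
  n <- nrow(xyz)
  S <- colSums(F^2) # self terms
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        S <- S + 2 * F[i, ] * F[j, ] * .sinc(q * d)
      }
    }
  }
  S
}

.check_qgrid <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || is.unsorted(q, strictly = TRUE)) {
    rlang::abort("`q` must be a strictly increasing non-negative grid (1/Angstrom).")
  }
}

#' Isotropic Debye scattering of the solute
#'
#' Orientationally averaged coherent scattering of the rigid three-iodine
#' solute: `S(q) = sum_ij Fi(q) Fj(q) sinc(q d_ij)`, with Debye-Waller-damped
#' atomic form factors and the `i = j` sinc term equal to 1. The `q -> 0`
#' and `d -> 0` limits are handled by series expansion of sinc.
#'
#' @param g A [solute_geometry()].
#' @param q Strictly increasing q grid in 1/Angstrom.
#' @param sigma Per-atom rmsd values, see [dw_params()].
#' @return A tibble with columns `q` and `S` (electron units per molecule).
#' @examples
#' g <- solute_geometry(2.95, 3.06, deg2rad(172))
#' debye_scattering(g, seq(0.5, 4.5, 0.1))
#' @export
debye_scattering <- function(g, q, sigma = dw_params()) {
  .check_qgrid(q)
  tibble::tibble(q = q, S = .debye_curve(g, q, dw_params(sigma)))
}

.debye_curve <- function(g, q, sigma) {
  xyz <- solute_coords(g)
  d <- stats::dist(xyz)
  if (any(d < 1e-8)) rlang::abort("Degenerate geometry: coincident atoms.")
  F <- .ff_matrix(q, sigma, c("I", "I", "I"))
  .debye_sum(q, F, xyz)
}

#' Anisotropic (P2) difference scattering of a photoselected solute
#'
#' The leading anisotropic component created by photoselection with
#' linearly polarized light:
#' `S2(q) = c2 * sum_{i != j} Fi(q) Fj(q) P2(cos zeta_ij) j2(q d_ij)`,
#' where `zeta_ij` is the angle between the interatomic vector and the
#' transition dipole. Self-terms carry no orientational information and are
#' excluded. Sign convention: the sum is taken with a positive prefactor,
#' so for a dipole along the long molecular axis the near-axis pairs
#' (P2 ~ 1) contribute with the sign of `c2`; the synthetic-data generator
#' and the fitted amplitude `A_ani` share this convention.
#'
#' @inheritParams debye_scattering
#' @param dipole Unit transition-dipole vector, see [dipole_axis()].
#' @param c2 Dimensionless amplitude (absorbed into `A_ani(t)` in the
#'   time-dependent model; keep 1 here).
#' @return A tibble with columns `q` and `S2`.
#' @export
anisotropic_scattering <- function(g, q, dipole = dipole_axis(g), c2 = 1,
                                   sigma = dw_params()) {
  .check_qgrid(q)
  n <- sqrt(sum(dipole^2))
  if (!is.finite(n) || n < 1e-12) rlang::abort("Transition dipole has zero norm.")
  tibble::tibble(q = q, S2 = .aniso_curve(g, q, dipole / n, c2, dw_params(sigma)))
}

.aniso_curve <- function(g, q, dipole, c2, sigma) {
  xyz <- solute_coords(g)
  F <- .ff_matrix(q, sigma, c("I", "I", "I"))
  S2 <- numeric(length(q))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      v <- xyz[i, ] - xyz[j, ]
      d <- sqrt(sum(v^2))
      cz <- sum(v * dipole) / d
      P2 <- 0.5 * (3 * cz^2 - 1)
      S2 <- S2 + 2 * F[i, ] * F[j, ] * P2 * .sph_j2(q * d)
    }
  }
  c2 * S2
}

#' Difference solute scattering between two structures
#'
#' `dS(q) = S(q; excited) - S(q; ground)`, both evaluated with the same
#' Debye-Waller damping.
#'
#' @param g_es,g_gs Excited- and ground-state [solute_geometry()].
#' @inheritParams debye_scattering
#' @return A tibble with columns `q` and `dS`.
#' @export
difference_solute <- function(g_es, g_gs, q, sigma = dw_params()) {
  .check_qgrid(q)
  sigma <- dw_params(sigma)
  tibble::tibble(q = q, dS = .debye_curve(g_es, q, sigma) - .debye_curve(g_gs, q, sigma))
}
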