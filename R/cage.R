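# Per-solvent constants: atomic number densities (atoms/A^3) from bulk mass
# density and composition, the non-hydrogen contact element seen by a
# dissociating iodine, the triiodide ground-state geometry, the mean
# electron density (e/A^3, for the displaced-volume term) and the position
# of the main diffraction peak (1/A, for the synthetic heating reference).
.solvent_table <- list(
  acetonitrile = list(
    densities = c(C = 0.02306, N = 0.01153, H = 0.03459),
    contact = "C", gs = c(2.95, 3.06, 172), rho_e = 0.254, q_peak = 1.8),
  water = list(
    densities = c(O = 0.03340, H = 0.06680),
    contact = "O", gs = c(2.92, 3.14, 170), rho_e = 0.334, q_peak = 2.0),
  ethanol = list(
    densities = c(C = 0.02063, O = 0.01031, H = 0.06189),
    contact = "O", gs = c(2.94, 3.07, 171), rho_e = 0.268, q_peak = 1.5),
  methanol = list(
    densities = c(C = 0.01489, O = 0.01489, H = 0.05955),
    contact = "O", gs = c(2.94, 3.09, 172), rho_e = 0.268, q_peak = 1.7)
)

#' Solvent specification
#'
#' Bundles the per-solvent inputs of the cage and heating terms: atomic
#' number densities, the non-hydrogen contact element (O for water and the
#' alcohols, C for acetonitrile), the triiodide ground-state geometry in
#' that solvent, and the bulk electron density.
#'
#' @param name One of `"acetonitrile"`, `"water"`, `"ethanol"`, `"methanol"`.
#' @return An object of class `solvent_spec`.
#' @examples
#' sv <- solvent_spec("acetonitrile")
#' sv$gs_geometry
#' @export
solvent_spec <- function(name = c("acetonitrile", "water", "ethanol", "methanol")) {
  name <- match.arg(name)
  s <- .solvent_table[[name]]
  structure(list(
    name = name,
    densities = s$densities,
    contact = s$contact,
    gs_geometry = solute_geometry(s$gs[1], s$gs[2], deg2rad(s$gs[3])),
    rho_e = s$rho_e,
    q_peak = s$q_peak
  ), class = "solvent_spec")
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat(sprintf("<solvent_spec> %s; contact atom %s; GS r12=%.2f r23=%.2f alpha=%.0f deg\n",
              x$name, x$contact, x$gs_geometry$r12, x$gs_geometry$r23,
              rad2deg(x$gs_geometry$alpha)))
  invisible(x)
}

#' First-solvation-shell parameters for the synthetic RDF model
#'
#' The parametric radial distribution functions stand in for the
#' frozen-solute MD library: an excluded core below `r_core`, a Gaussian
#' first-shell peak at `r_peak` of width `width` and height `amplitude`
#' (relative to bulk), decaying to `g = 1`. `coupling` shifts the shell
#' position around each terminal iodine linearly with the change of that
#' atom's nearest-neighbour I-I distance (saturating at `cap`); the
#' default 0 gives geometry-independent shells.
#'
#' @param r_peak First-shell position (Angstrom).
#' @param width Gaussian shell width (Angstrom), positive.
#' @param amplitude Peak height above bulk (dimensionless, `g_max = 1 + amplitude`).
#' @param r_core Hard-core exclusion radius (Angstrom).
#' @param coupling Dimensionless linear geometry coupling of the shell position.
#' @param cap Saturation distance for the coupling rule (Angstrom).
#' @return An object of class `shell_params`.
#' @export
shell_params <- function(r_peak = 3.5, width = 0.4, amplitude = 0.8,
                         r_core = 2.6, coupling = 0, cap = 5.5) {
  if (!is.finite(width) || width <= 0) rlang::abort("Shell `width` must be positive.")
  if (r_core < 0 || r_peak <= r_core) rlang::abort("Need 0 <= r_core < r_peak.")
  structure(list(r_peak = r_peak, width = width, amplitude = amplitude,
                 r_core = r_core, coupling = coupling, cap = cap),
            class = "shell_params")
}

# One smooth parametric g(r): 0 inside the core, then a tapered rise to
# bulk plus a Gaussian first-shell peak.
.rdf_profile <- function(r, r_peak, width, amplitude, r_core) {
  g <- numeric(length(r))
  out <- r >= r_core
  ro <- r[out]
  taper <- 1 - exp(-((ro - r_core) / 0.3)^2)
  g[out] <- taper * (1 + amplitude * exp(-(ro - r_peak)^2 / (2 * width^2)))
  g
}

#' Synthetic solute-solvent radial distribution functions
#'
#' Generates smooth per-atom, per-solvent-type RDFs `g_Iv(r)` for a given
#' solute geometry. Hydrogen shells sit 0.4 Angstrom beyond the heavy-atom
#' shell at reduced amplitude and a smaller core; the shell around the
#' buried central iodine is attenuated. With nonzero `coupling` the shell
#' around each terminal iodine tracks that atom's nearest-neighbour
#' distance (relative to the solvent's ground-state geometry).
#'
#' @param g A [solute_geometry()].
#' @param solvent A [solvent_spec()].
#' @param r Radial grid (Angstrom), strictly increasing.
#' @param shell A [shell_params()].
#' @return Object of class `rdf_set`: list with `r`, a 3 x types x length(r)
#'   array `g`, and the generating solvent/shell.
#' @export
synth_rdf <- function(g, solvent, r = seq(0, 12, by = 0.04),
                      shell = shell_params()) {
  stopifnot(inherits(g, "solute_geometry"), inherits(solvent, "solvent_spec"),
            inherits(shell, "shell_params"))
  types <- names(solvent$densities)
  d <- pair_distances(g)
  d_gs <- pair_distances(solvent$gs_geometry)
  nn <- function(dm, i) min(dm[i, -i])
  arr <- array(0, dim = c(3, length(types), length(r)),
               dimnames = list(c("I1", "I2", "I3"), types, NULL))
  for (i in 1:3) {
    shift <- shell$coupling * (min(nn(d, i), shell$cap) - min(nn(d_gs, i), shell$cap))
    amp_scale <- if (i == 2) 0.5 else 1 # central atom is solvent-shielded
    for (v in seq_along(types)) {
      if (types[v] == "H") {
        arr[i, v, ] <- .rdf_profile(r, shell$r_peak + shift + 0.4, shell$width * 1.2,
                                    0.35 * shell$amplitude * amp_scale,
                                    max(shell$r_core - 0.6, 0))
      } else {
        arr[i, v, ] <- .rdf_profile(r, shell$r_peak + shift, shell$width,
                                    shell$amplitude * amp_scale, shell$r_core)
      }
    }
  }
  structure(list(r = r, g = arr, solvent = solvent$name, shell = shell),
            class = "rdf_set")
}

#' Tidy a set of radial distribution functions
#' @param x An `rdf_set` from [synth_rdf()].
#' @param ... Unused.
#' @return Tibble with columns `atom`, `type`, `r`, `g`.
#' @method tidy rdf_set
#' @export
tidy.rdf_set <- function(x, ...) {
  dn <- dimnames(x$g)
  tidyr::expand_grid(atom = dn[[1]], type = dn[[2]]) |>
    dplyr::rowwise() |>
    dplyr::reframe(atom = .data$atom, type = .data$type, r = x$r,
                   g = x$g[.data$atom, .data$type, ])
}

# Trapezoid weights for an arbitrary strictly increasing grid.
.trap_weights <- function(r) {
  n <- length(r)
  w <- numeric(n)
  w[1] <- (r[2] - r[1]) / 2
  w[n] <- (r[n] - r[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / 2
  w
}

# Cosine taper over the last `frac` of the radial grid, applied to (g - 1)
# to suppress truncation ringing of the Fourier integral.
.tail_taper <- function(r, frac = 0.1) {
  r0 <- r[length(r)] - frac * (r[length(r)] - r[1])
  w <- rep(1, length(r))
  tail <- r > r0
  w[tail] <- 0.5 * (1 + cos(pi * (r[tail] - r0) / (r[length(r)] - r0)))
  w
}

#' Solute-solvent cage cross term
#'
#' Difference-scattering building block from the structured solvent around
#' the solute:
#' `S_cross(q) = sum_i sum_v F_I(q) F_v(q) 4 pi rho_v Int r^2 (g_iv(r)-1) sinc(q r) dr`,
#' evaluated by trapezoidal quadrature on the RDF's radial grid with a
#' cosine taper of `(g - 1)` over the last 10% of the grid. If the RDFs
#' have not converged to bulk at the grid edge a warning is issued.
#'
#' @param rdfs An `rdf_set` from [synth_rdf()].
#' @param solvent A [solvent_spec()] (supplies densities and atom types).
#' @param q Strictly increasing q grid (1/Angstrom).
#' @return A tibble with columns `q` and `S_cross` (electron units per solute).
#' @export
cage_cross_term <- function(rdfs, solvent, q) {
  .check_qgrid(q)
  tibble::tibble(q = q, S_cross = .cross_curve(rdfs, solvent, q))
}

.cross_curve <- function(rdfs, solvent, q) {
  r <- rdfs$r
  types <- dimnames(rdfs$g)[[2]]
  edge <- rdfs$g[, , length(r)]
  if (any(abs(edge - 1) > 0.02)) {
    rlang::warn("RDF not converged to bulk at the radial grid edge; taper applied.")
  }
  wq <- .trap_weights(r) * .tail_taper(r) * r^2
  K <- .sinc(outer(q, r)) # nq x nr
  fI <- atomic_form_factor(q, "I")
  S <- numeric(length(q))
  for (v in seq_along(types)) {
    wsum <- colSums(rdfs$g[, v, , drop = FALSE][, 1, ] - 1) # sum over the 3 iodines
    integral <- as.numeric(K %*% (wq * wsum))
    S <- S + fI * atomic_form_factor(q, types[v]) *
      4 * pi * solvent$densities[[v]] * integral
  }
  S
}

#' Displaced-volume (excluded solvent) term
#'
#' Scattering contribution of the solvent volume excluded by the solute,
#' modelled as a Gaussian dummy-solvent sphere at each iodine site with
#' form factor `f_dv(q) = rho_e V exp(-q^2 V^(2/3) / (4 pi))`
#' (Fraser-MacRae-Suzuki convention), where `V` is the sphere volume of
#' radius `r_excl`. The returned curve is the dummy-dummy Debye sum minus
#' twice the solute-dummy cross sum (the terms by which displaced solvent
#' modifies the total intensity); set `include_solute_cross = FALSE` for
#' the pure dummy-sphere intensity.
#'
#' @param g A [solute_geometry()] (dummy sites are co-located with the atoms).
#' @param solvent A [solvent_spec()] (supplies the electron density).
#' @param q Strictly increasing q grid (1/Angstrom).
#' @param r_excl Excluded-sphere radius (Angstrom); default the iodine
#'   van der Waals radius 1.98.
#' @param include_solute_cross Include the solute-dummy cross term.
#' @param sigma Solute Debye-Waller rmsd values (for the cross term).
#' @return A tibble with columns `q` and `S_dv`.
#' @export
displaced_volume_term <- function(g, solvent, q, r_excl = 1.98,
                                  include_solute_cross = TRUE,
                                  sigma = dw_params()) {
  .check_qgrid(q)
  if (!is.finite(r_excl) || r_excl < 0) rlang::abort("`r_excl` must be >= 0.")
  tibble::tibble(q = q, S_dv = .dv_curve(g, solvent, q, r_excl,
                                         include_solute_cross, dw_params(sigma)))
}

.dv_curve <- function(g, solvent, q, r_excl, include_solute_cross, sigma) {
  if (r_excl == 0) return(numeric(length(q)))
  V <- 4 / 3 * pi * r_excl^3
  fdv <- solvent$rho_e * V * exp(-q^2 * V^(2 / 3) / (4 * pi))
  xyz <- solute_coords(g)
  Fd <- rbind(fdv, fdv, fdv)
  S <- .debye_sum(q, Fd, xyz)
  if (include_solute_cross) {
    FI <- .ff_matrix(q, sigma, c("I", "I", "I"))
    cross <- numeric(length(q))
    for (i in 1:3) {
      for (j in 1:3) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        cross <- cross + FI[i, ] * fdv * .sinc(q * d)
      }
    }
    S <- S - 2 * cross
  }
  S
}

#' First solvation shell radius from an RDF
#'
#' Position of the first local maximum of `g(r)` above bulk, with optional
#' running-mean smoothing and parabolic sub-bin refinement.
#'
#' @param r Radial grid (Angstrom).
#' @param g RDF values on `r`.
#' @param smooth Odd window length for running-mean smoothing (0 = none).
#' @param prominence Minimum peak height above bulk (`g > 1 + prominence`).
#' @return First-peak radius in Angstrom.
#' @export
first_shell_radius <- function(r, g, smooth = 0, prominence = 0.05) {
  stopifnot(length(r) == length(g))
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    g <- stats::filter(g, k, sides = 2)
    keep <- !is.na(g)
    r <- r[keep]; g <- as.numeric(g[keep])
  }
  n <- length(g)
  i <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n] &
               g[2:(n - 1)] > 1 + prominence) + 1
  if (length(i) == 0) rlang::abort("No solvation-shell peak above bulk found in g(r).")
  i <- i[1]
  # parabolic vertex through the three points around the grid argmax
  y1 <- g[i - 1]; y2 <- g[i]; y3 <- g[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-14) 0.5 * (y1 - y3) / denom else 0
  r[i] + delta * (r[i + 1] - r[i])
}
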