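#' Structural grid for the cage (RDF) library
#'
#' Axes of the (r12, r23, alpha) grid on which cage cross-term curves are
#' tabulated. Axes must be strictly increasing with uniform steps. The
#' full-size grid of the underlying methodology runs r12 = 2.6-5.0 (step
#' 0.2 Angstrom), r23 = 2.6-13.8 (step 0.2) and alpha = 0-pi (step 0.131
#' rad); coarser grids are adequate for the parametric RDF model and much
#' cheaper to build.
#'
#' @param r12,r23 Axis vectors in Angstrom.
#' @param alpha Axis vector in radians, within `[0, pi]`.
#' @return An object of class `cage_grid`; `n_nodes` reports the node count.
#' @export
cage_grid <- function(r12 = seq(2.6, 5.0, by = 0.2),
                      r23 = seq(2.6, 13.8, by = 0.2),
                      alpha = seq(0, pi, length.out = 25)) {
  check_axis <- function(x, nm) {
    if (length(x) < 2 || is.unsorted(x, strictly = TRUE)) {
      rlang::abort(paste0("Grid axis `", nm, "` must be strictly increasing."))
    }
    st <- diff(x)
    if (max(st) - min(st) > 1e-8 * max(st)) {
      rlang::abort(paste0("Grid axis `", nm, "` must have uniform steps."))
    }
    x
  }
  structure(list(r12 = check_axis(r12, "r12"), r23 = check_axis(r23, "r23"),
                 alpha = check_axis(alpha, "alpha")),
            class = "cage_grid")
}

#' @export
print.cage_grid <- function(x, ...) {
  cat(sprintf("<cage_grid> %d x %d x %d = %d nodes\n", length(x$r12),
              length(x$r23), length(x$alpha), n_nodes(x)))
  invisible(x)
}

#' @rdname cage_grid
#' @param grid A `cage_grid`.
#' @export
n_nodes <- function(grid) length(grid$r12) * length(grid$r23) * length(grid$alpha)

#' Build a cage cross-term library on a structural grid
#'
#' For every grid node the synthetic RDFs are generated and reduced to the
#' cage cross-term curve on the q grid; off-node geometries are later
#' evaluated by trilinear interpolation (see [interpolate_cage()]). The
#' build is deterministic given the grid, shell parameters and solvent.
#'
#' @param grid A [cage_grid()].
#' @param solvent A [solvent_spec()].
#' @param q Strictly increasing q grid (1/Angstrom).
#' @param r Radial grid for the RDFs (Angstrom).
#' @param shell A [shell_params()]; use nonzero `coupling` for
#'   geometry-dependent cages.
#' @return An object of class `rdf_library` holding the grid, q grid and a
#'   4-d array of node curves.
#' @export
build_rdf_library <- function(grid, solvent, q, r = seq(0, 12, by = 0.04),
                              shell = shell_params()) {
  stopifnot(inherits(grid, "cage_grid"), inherits(solvent, "solvent_spec"))
  .check_qgrid(q)
  n1 <- length(grid$r12); n2 <- length(grid$r23); n3 <- length(grid$alpha)
  cross <- array(NA_real_, dim = c(n1, n2, n3, length(q)))
  if (shell$coupling == 0) {
    # geometry-independent shells: every node shares one curve
    g0 <- solute_geometry(grid$r12[1], grid$r23[1], grid$alpha[1])
    curve <- withCallingHandlers(
      .cross_curve(synth_rdf(g0, solvent, r, shell), solvent, q),
      warning = function(w) invokeRestart("muffleWarning"))
    cross[] <- rep(curve, each = n1 * n2 * n3)
  } else {
    for (i3 in seq_len(n3)) {
      a <- min(grid$alpha[i3], pi)
      for (i2 in seq_len(n2)) {
        for (i1 in seq_len(n1)) {
          gnode <- solute_geometry(grid$r12[i1], grid$r23[i2], a)
          rdfs <- synth_rdf(gnode, solvent, r, shell)
          cross[i1, i2, i3, ] <- withCallingHandlers(
            .cross_curve(rdfs, solvent, q),
            warning = function(w) invokeRestart("muffleWarning"))
        }
      }
    }
  }
  structure(list(grid = grid, q = q, cross = cross, shell = shell,
                 solvent = solvent$name, r = r),
            class = "rdf_library")
}

#' @export
print.rdf_library <- function(x, ...) {
  cat(sprintf("<rdf_library> %s, %d nodes, %d q points\n", x$solvent,
              n_nodes(x$grid), length(x$q)))
  invisible(x)
}

# Locate a coordinate on an axis; returns the lower cell index and the
# fractional position, clamping to the hull.
.locate <- function(x, axis) {
  n <- length(axis)
  clamped <- x < axis[1] - 1e-12 || x > axis[n] + 1e-12
  x <- min(max(x, axis[1]), axis[n])
  i <- findInterval(x, axis, rightmost.closed = TRUE)
  i <- min(max(i, 1L), n - 1L)
  list(i = i, f = (x - axis[i]) / (axis[i + 1] - axis[i]), clamped = clamped)
}

.interp_cross <- function(r12, r23, alpha, lib, warn = TRUE) {
  l1 <- .locate(r12, lib$grid$r12)
  l2 <- .locate(r23, lib$grid$r23)
  l3 <- .locate(alpha, lib$grid$alpha)
  if (warn && (l1$clamped || l2$clamped || l3$clamped)) {
    rlang::warn("Geometry outside the cage-library hull; clamped to the grid edge.")
  }
  S <- 0
  for (d1 in 0:1) {
    w1 <- if (d1 == 0) 1 - l1$f else l1$f
    if (w1 == 0) next
    for (d2 in 0:1) {
      w2 <- if (d2 == 0) 1 - l2$f else l2$f
      if (w2 == 0) next
      for (d3 in 0:1) {
        w3 <- if (d3 == 0) 1 - l3$f else l3$f
        if (w3 == 0) next
        S <- S + w1 * w2 * w3 * lib$cross[l1$i + d1, l2$i + d2, l3$i + d3, ]
      }
    }
  }
  S
}

#' Trilinear interpolation of cage curves at an off-node geometry
#'
#' Per-q trilinear interpolation over the 8 grid nodes enclosing
#' `(r12, r23, alpha)`. Geometries outside the grid hull are clamped to
#' the nearest edge with a warning (e.g. the solvent-separated species at
#' r23 = 100 Angstrom uses the largest tabulated r23, where the cage term
#' is already fragment-like).
#'
#' @param g A [solute_geometry()].
#' @param library An [build_rdf_library()] result.
#' @param warn Warn when clamping out-of-hull geometries.
#' @return A tibble with columns `q` and `S_cross`.
#' @export
interpolate_cage <- function(g, library, warn = TRUE) {
  stopifnot(inherits(g, "solute_geometry"), inherits(library, "rdf_library"))
  tibble::tibble(q = library$q,
                 S_cross = .interp_cross(g$r12, g$r23, g$alpha, library, warn))
}

#' Cage difference scattering between two geometries
#'
#' `dS_cage = [S_cross(es) - S_cross(gs)] + [S_dv(es) - S_dv(gs)]`, with
#' the cross terms taken from the interpolated library and the
#' displaced-volume terms evaluated directly.
#'
#' @param g_es,g_gs Excited- and ground-state [solute_geometry()].
#' @param library An [build_rdf_library()] result.
#' @param solvent A [solvent_spec()].
#' @param r_excl Excluded-sphere radius for the displaced-volume term.
#' @param warn Warn on out-of-hull clamping.
#' @return A tibble with columns `q` and `dS_cage`.
#' @export
cage_difference <- function(g_es, g_gs, library, solvent, r_excl = 1.98,
                            warn = TRUE) {
  q <- library$q
  d_cross <- .interp_cross(g_es$r12, g_es$r23, g_es$alpha, library, warn) -
    .interp_cross(g_gs$r12, g_gs$r23, g_gs$alpha, library, warn)
  d_dv <- .dv_curve(g_es, solvent, q, r_excl, TRUE, dw_params()) -
    .dv_curve(g_gs, solvent, q, r_excl, TRUE, dw_params())
  tibble::tibble(q = q, dS_cage = d_cross + d_dv)
}
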