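#' Triiodide solute geometry
#'
#' The three-iodine arrangement is described by the I1-I2 distance `r12`
#' (the nascent I2- bond), the I2-I3 distance `r23` (the dissociation
#' coordinate) and the I-I-I angle `alpha` at the central atom. The
#' remaining distance d13 follows from the law of cosines.
#'
#' @param r12,r23 Interatomic distances in Angstrom, strictly positive.
#' @param alpha I-I-I angle in radians, in `[0, pi]`.
#' @return An object of class `solute_geometry`.
#' @examples
#' g <- solute_geometry(2.95, 3.06, deg2rad(172)) # triiodide in acetonitrile
#' pair_distances(g)
#' @export
solute_geometry <- function(r12, r23, alpha) {
  if (!is.finite(r12) || r12 <= 0 || !is.finite(r23) || r23 <= 0) {
    rlang::abort("Distances `r12` and `r23` must be positive (Angstrom).")
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > pi) {
    rlang::abort("`alpha` must lie in [0, pi] radians.")
  }
  structure(list(r12 = r12, r23 = r23, alpha = alpha),
            class = "solute_geometry")
}

#' @export
print.solute_geometry <- function(x, ...) {
  cat(sprintf("<solute_geometry> r12 = %.3f A, r23 = %.3f A, alpha = %.1f deg\n",
              x$r12, x$r23, rad2deg(x$alpha)))
  invisible(x)
}

#' Degree/radian helpers
#' @param deg Angle in degrees.
#' @return Angle in radians (`deg2rad`) or degrees (`rad2deg`).
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname deg2rad
#' @param rad Angle in radians.
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Cartesian coordinates of the three iodine atoms
#'
#' Places I2 at the origin, I1 on the negative x axis, and I3 in the xy
#' plane such that the angle I1-I2-I3 equals `alpha`. For the nearly
#' linear ion (`alpha` close to pi) I1 and I3 sit on opposite sides.
#'
#' @param g A [solute_geometry()].
#' @return A 3x3 matrix with rows I1, I2, I3 (Angstrom).
#' @export
solute_coords <- function(g) {
  stopifnot(inherits(g, "solute_geometry"))
  rbind(
    I1 = c(-g$r12, 0, 0),
    I2 = c(0, 0, 0),
    I3 = g$r23 * c(-cos(g$alpha), sin(g$alpha), 0)
  )
}

#' Pairwise interatomic distances
#'
#' @param g A [solute_geometry()].
#' @return Symmetric 3x3 matrix of distances in Angstrom.
#' @export
pair_distances <- function(g) {
  xyz <- solute_coords(g)
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(rownames(xyz), rownames(xyz))
  d
}

#' Transition-dipole convention
#'
#' Direction of the transition dipole moment in the molecular frame used
#' for photoselection. The default, `"long_axis"`, points along the
#' end-to-end I1 -> I3 vector of the quasi-linear ion, the conventional
#' choice for the 400 nm axis-polarized excitation.
#'
#' @param g A [solute_geometry()] (needed to resolve `"long_axis"`).
#' @param axis Either the string `"long_axis"` or a numeric length-3
#'   vector (will be normalized; must have nonzero norm).
#' @return Unit numeric vector of length 3.
#' @export
dipole_axis <- function(g, axis = "long_axis") {
  if (identical(axis, "long_axis")) {
    xyz <- solute_coords(g)
    v <- xyz["I3", ] - xyz["I1", ]
  } else {
    v <- as.numeric(axis)
    if (length(v) != 3) rlang::abort("`axis` must be length 3 or 'long_axis'.")
  }
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-12) rlang::abort("Transition dipole has zero norm.")
  v / n
}
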