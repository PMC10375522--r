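#' Default synthetic scenario
#'
#' The standard study conditions used throughout the tests and examples:
#' acetonitrile, q = 0.5-4.5 1/Angstrom in steps of 0.02 (201 points), 41
#' time delays from -0.1 to 500 ps (linear to 1 ps, logarithmic beyond),
#' the default acetonitrile-regime [reaction_scheme()], 1% homoscedastic
#' noise, and a coarse cage library (7 x 15 x 13 nodes) with
#' geometry-coupled solvation shells so that the trilinear-interpolation
#' path is exercised.
#'
#' @param solvent Solvent name.
#' @param noise Noise level (fraction of peak `|dS0|`).
#' @param seed Integer seed for the dataset noise.
#' @param scheme A [reaction_scheme()].
#' @return List with `solvent`, `q`, `t`, `scheme`, `library`, `ctx`,
#'   `truth` and `dataset`.
#' @export
default_scenario <- function(solvent = "acetonitrile", noise = 0.01, seed = 1,
                             scheme = reaction_scheme()) {
  sv <- solvent_spec(solvent)
  q <- seq(0.5, 4.5, by = 0.02)
  t <- c(seq(-0.1, 1, by = 0.05),
         10^seq(log10(1.3), log10(500), length.out = 18))
  lib <- build_rdf_library(
    cage_grid(r12 = seq(2.6, 3.8, by = 0.2),
              r23 = seq(2.6, 13.8, by = 0.8),
              alpha = seq(0, pi, length.out = 13)),
    sv, q, shell = shell_params(coupling = 0.25))
  ctx <- forward_context(sv, q, lib)
  truth <- simulate_trajectory(scheme, t, sv$gs_geometry)
  dataset <- simulate_dataset(truth, ctx, noise = noise, seed = seed)
  list(solvent = sv, q = q, t = t, scheme = scheme, library = lib,
       ctx = ctx, truth = truth, dataset = dataset)
}
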