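# Shared small fixtures, built once per test run. The q grid and cage
# library are deliberately coarse: the physics is identical, only the
# resolution differs from the default scenario.
.fixtures <- new.env(parent = emptyenv())

tiny_q <- function() seq(0.5, 4.5, by = 0.05)

tiny_library <- function() {
  if (is.null(.fixtures$lib)) {
    .fixtures$lib <- build_rdf_library(
      cage_grid(r12 = seq(2.6, 3.8, by = 0.3),
                r23 = seq(2.6, 13.8, by = 1.6),
                alpha = seq(0, pi, length.out = 5)),
      solvent_spec("acetonitrile"), tiny_q(),
      r = seq(0, 12, by = 0.05), shell = shell_params(coupling = 0.25))
  }
  .fixtures$lib
}

tiny_ctx <- function() {
  if (is.null(.fixtures$ctx)) {
    .fixtures$ctx <- forward_context(solvent_spec("acetonitrile"), tiny_q(),
                                     tiny_library())
  }
  .fixtures$ctx
}

# Short noiseless trajectory + dataset on the tiny context.
tiny_truth <- function() {
  if (is.null(.fixtures$truth)) {
    t <- c(-0.1, seq(0.05, 0.9, by = 0.12), 1.5, 3, 10, 50)
    .fixtures$truth <- simulate_trajectory(reaction_scheme(), t,
                                           solvent_spec("acetonitrile")$gs_geometry)
  }
  .fixtures$truth
}

tiny_dataset <- function(noise = 0, seed = 42) {
  key <- sprintf("ds_%g_%d", noise, seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_dataset(tiny_truth(), tiny_ctx(),
                                         noise = noise, seed = seed)
  }
  .fixtures[[key]]
}

truth_x <- function(truth, k) {
  x <- as.numeric(truth[k, c("r12", "r23", "alpha", "A_iso", "A_GP",
                             "A_heat", "A_ani")])
  names(x) <- c("r12", "r23", "alpha", "A_iso", "A_GP", "A_heat", "A_ani")
  x
}

# A small complete refinement, reused by the io/report tests.
tiny_refinement <- function() {
  if (is.null(.fixtures$ref)) {
    .fixtures$ref <- refine_series(tiny_dataset(noise = 0.01),
                                   tiny_ctx(),
                                   refinement_config(lambda = 30, restarts = 3,
                                                     seed = 5))
  }
  .fixtures$ref
}
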