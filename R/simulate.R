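# Gaussian-IRF convolution kernels, all analytic:
#  .erf_step : unit step (x) Gaussian
#  .emg      : exp(-t/tau) step (x) Gaussian (exponentially modified Gaussian)
#  .rise_conv: (1 - exp(-t/tau)) step (x) Gaussian
.irf_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.erf_step <- function(t, sigma) {
  if (sigma <= 0) return(as.numeric(t >= 0))
  stats::pnorm(t / sigma)
}

.emg <- function(t, tau, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(-t / tau), 0))
  # log-scale evaluation avoids overflow of exp(sigma^2 / 2 tau^2)
  exp(sigma^2 / (2 * tau^2) - t / tau +
        stats::pnorm(t / sigma - sigma / tau, log.p = TRUE))
}

.rise_conv <- function(t, tau, sigma) .erf_step(t, sigma) - .emg(t, tau, sigma)

#' Reaction-scheme parameters for the synthetic ground truth
#'
#' Parameterizes the photodissociation scheme used to generate synthetic
#' trajectories: ballistic separation of the I fragment at `v_true` and
#' angular speed `omega_true` until arrest by the solvent cage at
#' `arrest` (then relaxation towards the geminate-pair plateau
#' `plateau_r23` with time `tau_cage`), a vibrationally hot I2- bond that
#' starts stretched by `hot_stretch` and relaxes to `r12_eq` with
#' `tau_hot`, biexponential geminate recombination (`tau1` < `tau2`,
#' fast-component fraction `a1_frac`), cage escape to the
#' solvent-separated species with probability `pe_true` rising on
#' `tau_ng`, Gaussian IRF broadening of all amplitude dynamics
#' (`irf_fwhm`), exponential rotational dephasing of the anisotropy
#' (`ani0`, `tau_rot`) and a heating amplitude ramp (`heat0`,
#' `tau_heat`). Defaults mirror the acetonitrile narrative (arrest near
#' 5.5 Angstrom, 6 Angstrom/ps dissociation, Pe = 0.38, lifetimes 0.4
#' and 38 ps, IRF 0.175 ps).
#'
#' @param v_true Dissociation speed (Angstrom/ps).
#' @param omega_true Angular speed after bond breakage (rad/ps).
#' @param arrest Cage-arrest interfragment distance (Angstrom).
#' @param plateau_r23 Geminate-pair plateau distance (Angstrom).
#' @param tau_cage Relaxation time from arrest to plateau (ps).
#' @param pe_true Cage-escape probability, in `[0, 1]`.
#' @param tau1,tau2 Geminate recombination lifetimes (ps), `tau1 < tau2`.
#' @param a1_frac Fraction of the fast decay component, `A1/(A1+A2)`.
#' @param tau_ng Rise time of the solvent-separated population (ps).
#' @param a0 Peak excitation fraction.
#' @param r12_eq Equilibrium I2- bond length (Angstrom).
#' @param hot_stretch Initial bond stretch of the hot fragment (Angstrom).
#' @param tau_hot Hot-bond relaxation time (ps).
#' @param irf_fwhm Gaussian IRF full width at half maximum (ps).
#' @param ani0 Initial anisotropy amplitude.
#' @param tau_rot Rotational dephasing time (ps).
#' @param heat0 Asymptotic heating amplitude (reference-curve units).
#' @param tau_heat Heating ramp time (ps).
#' @return An object of class `reaction_scheme`.
#' @export
reaction_scheme <- function(v_true = 6.0, omega_true = 4.0, arrest = 5.5,
                            plateau_r23 = 4.0, tau_cage = 0.7,
                            pe_true = 0.38, tau1 = 0.4, tau2 = 38,
                            a1_frac = 0.7, tau_ng = 0.3, a0 = 0.1,
                            r12_eq = 3.15, hot_stretch = 0.2, tau_hot = 2,
                            irf_fwhm = 0.175, ani0 = 0.05, tau_rot = 2,
                            heat0 = 1, tau_heat = 10) {
  p <- as.list(environment())
  times <- c("tau_cage", "tau1", "tau2", "tau_ng", "tau_hot", "irf_fwhm",
             "tau_rot", "tau_heat")
  if (any(unlist(p[times]) <= 0)) rlang::abort("All time constants must be positive.")
  if (pe_true < 0 || pe_true > 1) rlang::abort("`pe_true` must be in [0, 1].")
  if (tau1 >= tau2) rlang::abort("Need `tau1` < `tau2`.")
  structure(p, class = "reaction_scheme")
}

#' Simulate a ground-truth parameter trajectory
#'
#' Evaluates the reaction scheme on a time grid: the geometry follows the
#' ballistic / cage-arrest path at the nominal delay, while all amplitude
#' dynamics are convolved analytically with the Gaussian IRF. Before
#' excitation the geometry equals the ground state and all amplitudes are
#' zero. The geminate amplitude product `A_iso * A_GP` is by construction
#' an IRF-convolved biexponential with lifetimes `tau1`, `tau2`.
#'
#' @param scheme A [reaction_scheme()].
#' @param t Time grid in ps (need not be uniform).
#' @param gs Ground-state [solute_geometry()].
#' @return A tibble (class `txs_trajectory`) with columns `t` and the
#'   seven model parameters; the scheme is attached as attribute `scheme`.
#' @export
simulate_trajectory <- function(scheme, t, gs) {
  stopifnot(inherits(scheme, "reaction_scheme"), inherits(gs, "solute_geometry"))
  p <- scheme
  if (p$arrest <= gs$r23) rlang::abort("Cage-arrest distance must exceed the GS r23.")
  sig <- .irf_sigma(p$irf_fwhm)
  t_arr <- (p$arrest - gs$r23) / p$v_true

  pos <- t > 0
  r23 <- rep(gs$r23, length(t))
  r23[pos & t <= t_arr] <- gs$r23 + p$v_true * t[pos & t <= t_arr]
  late <- pos & t > t_arr
  r23[late] <- p$plateau_r23 +
    (p$arrest - p$plateau_r23) * exp(-(t[late] - t_arr) / p$tau_cage)

  alpha <- rep(gs$alpha, length(t))
  alpha[pos] <- pmax(gs$alpha - p$omega_true * pmin(t[pos], t_arr), 0.15)

  r12 <- rep(gs$r12, length(t))
  r12[pos] <- p$r12_eq + (gs$r12 + p$hot_stretch - p$r12_eq) * exp(-t[pos] / p$tau_hot)

  n_gp <- p$a0 * (p$a1_frac * .emg(t, p$tau1, sig) +
                    (1 - p$a1_frac) * .emg(t, p$tau2, sig))
  n_ng <- p$a0 * p$pe_true * .rise_conv(t, p$tau_ng, sig)
  a_iso <- n_gp + n_ng
  a_gp <- ifelse(a_iso > 1e-12, n_gp / a_iso, 1)
  out <- tibble::tibble(
    t = t, r12 = r12, r23 = r23, alpha = alpha,
    A_iso = a_iso, A_GP = pmin(pmax(a_gp, 0), 1),
    A_heat = p$heat0 * .rise_conv(t, p$tau_heat, sig),
    A_ani = p$ani0 * .emg(t, p$tau_rot, sig)
  )
  attr(out, "scheme") <- p
  attr(out, "gs") <- gs
  class(out) <- c("txs_trajectory", class(out))
  out
}

#' Synthetic solvent-heating reference curve
#'
#' Deterministic stand-in for the measured bulk-heating difference signal:
#' a derivative-of-peak shape centred on the solvent's main diffraction
#' peak (positive below the peak, negative above, integrating to
#' approximately zero over the experimental q range).
#'
#' @param solvent A [solvent_spec()].
#' @param q Strictly increasing q grid (1/Angstrom).
#' @return A tibble with columns `q` and `dS_heat` (electron units per
#'   solute molecule per unit heating amplitude).
#' @export
simulate_heating_reference <- function(solvent, q) {
  stopifnot(inherits(solvent, "solvent_spec"))
  .check_qgrid(q)
  w <- 0.45
  tibble::tibble(q = q,
                 dS_heat = 60 * (solvent$q_peak - q) / w *
                   exp(-(q - solvent$q_peak)^2 / (2 * w^2)))
}

#' Simulate a noisy isotropic/anisotropic difference-scattering dataset
#'
#' Runs the forward model at every timepoint of a ground-truth trajectory
#' and adds seeded Gaussian noise. The default noise model is
#' homoscedastic at `noise` times the peak absolute isotropic signal;
#' `heteroscedastic = TRUE` adds a component proportional to the local
#' signal magnitude.
#'
#' @param truth A [simulate_trajectory()] result.
#' @param ctx A [forward_context()].
#' @param noise Noise level as a fraction of `max |dS0|`.
#' @param seed Integer seed (reproducible datasets).
#' @param heteroscedastic Add a 50% signal-proportional noise component.
#' @return An object of class `aniso_dataset`: q/t grids, `dS0`, `dS2`
#'   matrices (nq x nt), uncertainty matrices `err0`, `err2`, the solvent
#'   tag, and the generating truth.
#' @export
simulate_dataset <- function(truth, ctx, noise = 0.01, seed = 1,
                             heteroscedastic = FALSE) {
  stopifnot(inherits(truth, "txs_trajectory"), inherits(ctx, "forward_context"))
  nq <- length(ctx$q); nt <- nrow(truth)
  dS0 <- matrix(0, nq, nt); dS2 <- matrix(0, nq, nt)
  for (k in seq_len(nt)) {
    x <- as.numeric(truth[k, .param_names])
    names(x) <- .param_names
    dS0[, k] <- .model_iso_curve(x, ctx)
    dS2[, k] <- .model_aniso_curve(x, ctx)
  }
  s0 <- noise * max(abs(dS0))
  if (noise > 0) {
    err0 <- matrix(s0, nq, nt); err2 <- matrix(s0, nq, nt)
    if (heteroscedastic) {
      err0 <- err0 + 0.5 * noise * abs(dS0)
      err2 <- err2 + 0.5 * noise * abs(dS2)
    }
    withr::with_seed(seed, {
      dS0 <- dS0 + matrix(stats::rnorm(nq * nt, sd = err0), nq, nt)
      dS2 <- dS2 + matrix(stats::rnorm(nq * nt, sd = err2), nq, nt)
    })
  } else {
    # exact data still need positive uncertainties for chi-square weighting
    err0 <- matrix(1, nq, nt); err2 <- matrix(1, nq, nt)
  }
  structure(list(q = ctx$q, t = truth$t, dS0 = dS0, dS2 = dS2,
                 err0 = err0, err2 = err2, solvent = ctx$solvent$name,
                 truth = truth),
            class = "aniso_dataset")
}

#' @export
print.aniso_dataset <- function(x, ...) {
  cat(sprintf("<aniso_dataset> %s: %d q points x %d time points\n",
              x$solvent, length(x$q), length(x$t)))
  invisible(x)
}

#' Tidy an anisotropic dataset into long format
#' @param x An `aniso_dataset`.
#' @param ... Unused.
#' @return Tibble with columns `q`, `t`, `dS0`, `dS2`, `err0`, `err2`.
#' @method tidy aniso_dataset
#' @export
tidy.aniso_dataset <- function(x, ...) {
  tibble::tibble(
    q = rep(x$q, times = length(x$t)),
    t = rep(x$t, each = length(x$q)),
    dS0 = as.vector(x$dS0), dS2 = as.vector(x$dS2),
    err0 = as.vector(x$err0), err2 = as.vector(x$err2)
  )
}

# Azimuthal-slice geometry: flat detector, vertical laser polarization,
# small scattering angle, so cos(theta) = cos(phi) for azimuth phi.
.p2 <- function(x) 0.5 * (3 * x^2 - 1)

.slice_phi <- function(n_slices) (seq_len(n_slices) - 0.5) * 2 * pi / n_slices

#' Build an azimuthally sliced 2-d difference pattern
#'
#' Distributes isotropic and anisotropic components over `n_slices`
#' azimuthal sections of a (flat, small-angle) detector with vertical
#' laser polarization: `dS(q, phi_k) = dS0(q) + P2(cos phi_k) dS2(q)`.
#'
#' @param dS0,dS2 Curves on a common q grid.
#' @param q The q grid.
#' @param n_slices Number of azimuthal sections (>= 3; default 15).
#' @return Object of class `aniso_pattern`: `q`, slice centres `phi`,
#'   and an `nq x n_slices` matrix `pattern`.
#' @export
simulate_2d_pattern <- function(dS0, dS2, q, n_slices = 15) {
  stopifnot(length(dS0) == length(q), length(dS2) == length(q))
  if (n_slices < 3) rlang::abort("Need at least 3 azimuthal slices to decompose.")
  phi <- .slice_phi(n_slices)
  structure(list(q = q, phi = phi,
                 pattern = outer(dS0, rep(1, n_slices)) + outer(dS2, .p2(cos(phi)))),
            class = "aniso_pattern")
}

#' Decompose an azimuthally sliced pattern into dS0 and dS2
#'
#' Per-q linear least squares on the basis `{1, P2(cos phi_k)}` — the
#' exact inverse of [simulate_2d_pattern()] for noiseless input.
#'
#' @param pattern An `aniso_pattern`.
#' @return A tibble with columns `q`, `dS0`, `dS2`.
#' @export
decompose_anisotropy <- function(pattern) {
  stopifnot(inherits(pattern, "aniso_pattern"))
  p2 <- .p2(cos(pattern$phi))
  if (length(p2) < 3 || stats::sd(p2) < 1e-12) {
    rlang::abort("Azimuthal basis is collinear; cannot separate dS0 and dS2.")
  }
  X <- cbind(1, p2)
  beta <- solve(crossprod(X), crossprod(X, t(pattern$pattern)))
  tibble::tibble(q = pattern$q, dS0 = beta[1, ], dS2 = beta[2, ])
}
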