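#' Refinement configuration
#'
#' Settings of the regularized per-timepoint chi-square minimization:
#' the regularization factor `lambda` (quadratic penalty on parameter
#' jumps between consecutive timepoints, on the natural scales Angstrom /
#' rad / amplitude), the number of random multi-start repeats per
#' timepoint, the physically feasible start ranges, and the seed that
#' makes the whole refinement deterministic.
#'
#' @param lambda Regularization factor, `>= 0`. The default was chosen by
#'   an L-curve sweep on the default synthetic scenario (see the package
#'   vignette).
#' @param restarts Minimizations per timepoint (default 10). When a
#'   previous-timepoint optimum exists, the first start is a warm start
#'   from it; the remainder are drawn randomly from `start_ranges`.
#' @param start_ranges Named list of `c(lo, hi)` start ranges.
#' @param weights Per-parameter penalty weights (natural scales).
#' @param maxit Iteration cap of each local minimization.
#' @param seed Integer seed.
#' @return An object of class `refinement_config`.
#' @export
refinement_config <- function(lambda = 30, restarts = 10,
                              start_ranges = list(
                                r12 = c(2.7, 3.6), r23 = c(2.7, 6.5),
                                alpha = c(1.0, 3.1), A_iso = c(0.01, 0.2),
                                A_GP = c(0.05, 0.95), A_heat = c(0, 2),
                                A_ani = c(-0.5, 0.5)),
                              weights = c(r12 = 1, r23 = 1, alpha = 1,
                                          A_iso = 1, A_GP = 1, A_heat = 1,
                                          A_ani = 1),
                              maxit = 500, seed = 1) {
  if (!is.finite(lambda) || lambda < 0) rlang::abort("`lambda` must be >= 0.")
  if (restarts < 1) rlang::abort("`restarts` must be >= 1.")
  stopifnot(all(.param_names %in% names(start_ranges)),
            all(.param_names %in% names(weights)))
  structure(list(lambda = lambda, restarts = as.integer(restarts),
                 start_ranges = start_ranges, weights = weights[.param_names],
                 maxit = maxit, seed = as.integer(seed)),
            class = "refinement_config")
}

#' Chi-square of model against one timepoint
#'
#' `chi2 = sum_q ((dS0_data - dS0_model)/err0)^2 +
#'         sum_q ((dS2_data - dS2_model)/err2)^2`:
#' both the isotropic and the anisotropic contribution enter the misfit.
#'
#' @param x Parameter vector (named, see [param_vector()]).
#' @param data_t List with vectors `dS0`, `dS2`, `err0`, `err2` on the
#'   context's q grid.
#' @param ctx A [forward_context()].
#' @return Non-negative scalar.
#' @export
chi2 <- function(x, data_t, ctx) {
  if (any(data_t$err0 <= 0) || any(data_t$err2 <= 0)) {
    rlang::abort("Uncertainties must be strictly positive.")
  }
  sum(((data_t$dS0 - .model_iso_curve(x, ctx)) / data_t$err0)^2) +
    sum(((data_t$dS2 - .model_aniso_curve(x, ctx)) / data_t$err2)^2)
}

#' Regularization penalty on parameter jumps
#'
#' `f = lambda * sum_k w_k (x_k - x_prev_k)^2`, with per-parameter scale
#' weights `w_k` (unit weights on the natural scales by default).
#'
#' @param x,x_prev Parameter vectors (named alike).
#' @param lambda Regularization factor.
#' @param weights Named per-parameter weights.
#' @return Non-negative scalar; 0 when `x == x_prev` or `lambda == 0`.
#' @export
regularization_penalty <- function(x, x_prev, lambda,
                                   weights = refinement_config()$weights) {
  if (is.null(x_prev) || lambda == 0) return(0)
  nm <- intersect(names(weights), names(x))
  lambda * sum(weights[nm] * (x[nm] - x_prev[nm])^2)
}

# --- soft-bound reparameterization ------------------------------------------
# The optimizer works in an unconstrained z-space: logistic transforms keep
# r12, r23, alpha and A_GP inside physical boxes, softplus keeps A_iso >= 0,
# A_heat and A_ani are unconstrained.
.tr_bounds <- list(r12 = c(2.45, 4.1), r23 = c(2.45, 14.2), alpha = c(0.05, pi))

.logistic <- function(z) 1 / (1 + exp(-z))
.logit <- function(p) log(p / (1 - p))
.softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
.inv_softplus <- function(x) ifelse(x > 30, x, log(expm1(pmax(x, 1e-10))))

.z_to_x <- function(z) {
  x <- z
  for (nm in names(.tr_bounds)) {
    b <- .tr_bounds[[nm]]
    x[nm] <- b[1] + (b[2] - b[1]) * .logistic(z[nm])
  }
  x["A_iso"] <- .softplus(z["A_iso"])
  x["A_GP"] <- .logistic(z["A_GP"])
  x
}

.x_to_z <- function(x) {
  z <- x
  for (nm in names(.tr_bounds)) {
    b <- .tr_bounds[[nm]]
    p <- pmin(pmax((x[nm] - b[1]) / (b[2] - b[1]), 1e-6), 1 - 1e-6)
    z[nm] <- .logit(p)
  }
  z["A_iso"] <- .inv_softplus(x["A_iso"])
  z["A_GP"] <- .logit(pmin(pmax(x["A_GP"], 1e-6), 1 - 1e-6))
  z
}

.random_start <- function(ranges) {
  x <- vapply(.param_names, function(nm) stats::runif(1, ranges[[nm]][1],
                                                      ranges[[nm]][2]),
              numeric(1))
  names(x) <- .param_names
  x
}

#' Refine one timepoint by regularized multi-start minimization
#'
#' Minimizes `chi2(x) + f(x, x_prev)` with `restarts` local minimizations
#' (Nelder-Mead followed by a BFGS polish in the soft-bound z-space) from
#' randomly drawn feasible starting guesses, warm-starting the first
#' restart from `x_prev` when available. The lowest objective wins; ties
#' break to the earliest restart.
#'
#' @param data_t List with `dS0`, `dS2`, `err0`, `err2` at one timepoint.
#' @param x_prev Previous-timepoint optimum (or `NULL`: no penalty).
#' @param ctx A [forward_context()].
#' @param cfg A [refinement_config()].
#' @param seed Seed for the random starts.
#' @param anchor Optional informed starting guess used for the first
#'   restart when no `x_prev` exists (e.g. the ground state with zero
#'   amplitudes for a pre-excitation delay).
#' @param parsimony_margin When no `x_prev` exists (the unregularized
#'   start of a series), the full seven-parameter model is accepted only
#'   if it beats the no-excitation reduced model (A_iso = 0, heating
#'   amplitude solved in closed form, ground-state geometry) by more than
#'   this chi-square margin; otherwise the reduced solution is returned.
#'   This keeps a noise overfit at a signal-free first delay from seeding
#'   the regularization chain with arbitrary geometry.
#' @return List with `x` (optimum), `objective` (chi2 + f), `chi2`,
#'   `penalty`, `converged`, and per-restart diagnostics `restarts`.
#' @export
refine_timepoint <- function(data_t, x_prev, ctx, cfg = refinement_config(),
                             seed = cfg$seed, anchor = NULL,
                             parsimony_margin = 20) {
  obj_x <- function(x) {
    chi2(x, data_t, ctx) +
      regularization_penalty(x, x_prev, cfg$lambda, cfg$weights)
  }
  obj_z <- function(z) {
    names(z) <- .param_names
    v <- obj_x(.z_to_x(z))
    if (!is.finite(v)) 1e30 else v
  }
  starts <- withr::with_seed(seed, {
    s <- lapply(seq_len(cfg$restarts), function(i) .random_start(cfg$start_ranges))
    if (!is.null(x_prev)) {
      s[[1]] <- x_prev[.param_names]
    } else if (!is.null(anchor)) {
      s[[1]] <- anchor[.param_names]
    }
    s
  })
  runs <- lapply(seq_along(starts), function(i) {
    z0 <- .x_to_z(starts[[i]])
    fit <- stats::optim(z0, obj_z, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit, reltol = 1e-10))
    list(par = fit$par, value = fit$value, converged = fit$convergence == 0)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  # quasi-Newton polish of the most promising simplex results (the simplex
  # ranking alone is unreliable for picking the basin of the optimum)
  for (i in utils::head(order(vals), 3L)) {
    polish <- suppressWarnings(
      stats::optim(runs[[i]]$par, obj_z, method = "BFGS",
                   control = list(maxit = 150, reltol = 1e-12)))
    if (polish$value <= vals[i]) {
      improved <- vals[i] - polish$value
      runs[[i]]$par <- polish$par
      runs[[i]]$value <- polish$value
      vals[i] <- polish$value
      runs[[i]]$converged <- polish$convergence == 0 ||
        improved < 1e-8 * (1 + abs(polish$value))
    }
  }
  ibest <- which.min(vals) # which.min returns the earliest minimum
  zbest <- runs[[ibest]]$par
  names(zbest) <- .param_names
  xbest <- .z_to_x(zbest)
  conv <- runs[[ibest]]$converged
  if (is.null(x_prev)) {
    # parsimony guard for the unregularized chain start: heating-only
    # reduced model with its amplitude solved by linear least squares
    gs <- if (is.null(anchor)) {
      c(r12 = ctx$gs$r12, r23 = ctx$gs$r23, alpha = ctx$gs$alpha,
        A_iso = 0, A_GP = 0.5, A_heat = 0, A_ani = 0)
    } else {
      anchor[.param_names]
    }
    x_red <- gs
    x_red["A_iso"] <- 0
    x_red["A_ani"] <- 0
    x_red["A_heat"] <- sum(ctx$heating * data_t$dS0 / data_t$err0^2) /
      max(sum(ctx$heating^2 / data_t$err0^2), 1e-300)
    chi2_red <- chi2(x_red, data_t, ctx)
    if (chi2_red - vals[ibest] < parsimony_margin) {
      xbest <- x_red
      vals[ibest] <- chi2_red
      conv <- TRUE
    }
  }
  pen <- regularization_penalty(xbest, x_prev, cfg$lambda, cfg$weights)
  list(x = xbest, objective = vals[ibest], chi2 = vals[ibest] - pen,
       penalty = pen, converged = conv,
       restarts = tibble::tibble(
         restart = seq_along(runs), objective = vals,
         converged = vapply(runs, `[[`, logical(1), "converged")))
}

.data_at <- function(dataset, k) {
  list(dS0 = dataset$dS0[, k], dS2 = dataset$dS2[, k],
       err0 = dataset$err0[, k], err2 = dataset$err2[, k])
}

#' Sequential refinement of a full time series
#'
#' Refines each timepoint in increasing time order, regularizing every
#' timepoint (except the first) against the previous optimized parameter
#' vector.
#'
#' @param dataset An `aniso_dataset`.
#' @param ctx A [forward_context()].
#' @param cfg A [refinement_config()].
#' @param progress Print per-timepoint progress lines.
#' @return An object of class `txs_refinement` whose `$params` tibble has
#'   one row per timepoint: `t`, the seven parameters, `A_NG`, `chi2`,
#'   `objective` and `converged`.
#' @export
refine_series <- function(dataset, ctx, cfg = refinement_config(),
                          progress = FALSE) {
  stopifnot(inherits(dataset, "aniso_dataset"))
  ord <- order(dataset$t)
  # the first delay of a series precedes (or straddles) excitation, where
  # the excited-state geometry is unconstrained by data; the chain is
  # therefore anchored by regularizing the first timepoint against the
  # known pre-excitation reference (ground-state geometry, amplitudes 0),
  # exactly as later timepoints are regularized against their predecessor
  gs <- ctx$gs
  x_prev <- c(r12 = gs$r12, r23 = gs$r23, alpha = gs$alpha, A_iso = 0,
              A_GP = 0.5, A_heat = 0, A_ani = 0)
  rows <- vector("list", length(ord))
  for (step in seq_along(ord)) {
    k <- ord[step]
    # with lambda = 0 the series is exactly independent per-timepoint
    # refinement: no penalty and no warm start from the previous optimum
    res <- refine_timepoint(.data_at(dataset, k),
                            if (cfg$lambda > 0) x_prev else NULL, ctx, cfg,
                            seed = cfg$seed + step)
    x_prev <- res$x
    rows[[step]] <- tibble::tibble(
      t = dataset$t[k], !!!as.list(res$x), A_NG = 1 - res$x[["A_GP"]],
      chi2 = res$chi2, objective = res$objective, converged = res$converged)
    if (progress) {
      message(sprintf("t = %8.3f ps  chi2 = %10.1f  converged = %s",
                      dataset$t[k], res$chi2, res$converged))
    }
  }
  structure(list(params = dplyr::bind_rows(rows), config = cfg,
                 solvent = dataset$solvent, n_q = length(dataset$q)),
            class = "txs_refinement")
}

#' @export
print.txs_refinement <- function(x, ...) {
  cat(sprintf("<txs_refinement> %s: %d timepoints, lambda = %g\n",
              x$solvent, nrow(x$params), x$config$lambda))
  print(utils::head(x$params, 5))
  invisible(x)
}

#' @describeIn refine_series Long-format parameter trajectories.
#' @param x A `txs_refinement`.
#' @param ... Unused.
#' @method tidy txs_refinement
#' @export
tidy.txs_refinement <- function(x, ...) {
  tidyr::pivot_longer(x$params, cols = dplyr::all_of(c(.param_names, "A_NG")),
                      names_to = "parameter", values_to = "value")
}

#' @describeIn refine_series One-row fit summary.
#' @method glance txs_refinement
#' @export
glance.txs_refinement <- function(x, ...) {
  tibble::tibble(
    n_timepoints = nrow(x$params),
    n_q = x$n_q,
    lambda = x$config$lambda,
    total_chi2 = sum(x$params$chi2),
    median_chi2 = stats::median(x$params$chi2),
    all_converged = all(x$params$converged)
  )
}

#' Sensitivity-based parameter uncertainty at one timepoint
#'
#' Scans each parameter away from the optimum, holding the others fixed,
#' until the objective `chi2 + f` has increased by `delta` (default 1);
#' the crossing points bound the confidence interval. Directions with no
#' crossing inside the scan range (flat directions, e.g. the amplitude of
#' an absent species) are flagged and reported as unbounded on that side.
#'
#' @param x_opt Optimized parameter vector.
#' @param data_t Timepoint data (as in [refine_timepoint()]).
#' @param ctx A [forward_context()].
#' @param cfg A [refinement_config()].
#' @param x_prev Previous-timepoint optimum used in the penalty (or `NULL`).
#' @param delta Objective increase defining the interval (default 1).
#' @param max_range Named vector of maximal scan distances per parameter.
#' @return Tibble with columns `parameter`, `estimate`, `lower`, `upper`,
#'   `flat_lower`, `flat_upper`.
#' @export
parameter_uncertainty <- function(x_opt, data_t, ctx, cfg = refinement_config(),
                                  x_prev = NULL, delta = 1,
                                  max_range = c(r12 = 1, r23 = 2, alpha = 1.5,
                                                A_iso = 0.5, A_GP = 1,
                                                A_heat = 2, A_ani = 2)) {
  obj <- function(x) {
    chi2(x, data_t, ctx) +
      regularization_penalty(x, x_prev, cfg$lambda, cfg$weights)
  }
  f0 <- obj(x_opt)
  dom <- list(r12 = c(1e-3, Inf), r23 = c(1e-3, Inf), alpha = c(0, pi),
              A_iso = c(0, Inf), A_GP = c(0, 1), A_heat = c(-Inf, Inf),
              A_ani = c(-Inf, Inf))
  scan_dir <- function(nm, dir) {
    lim <- if (dir > 0) dom[[nm]][2] else dom[[nm]][1]
    edge <- x_opt[[nm]] + dir * max_range[[nm]]
    edge <- if (dir > 0) min(edge, lim) else max(edge, lim)
    g <- function(s) {
      x <- x_opt; x[nm] <- s
      obj(x) - f0 - delta
    }
    if (abs(edge - x_opt[[nm]]) < 1e-12 || g(edge) < 0) {
      return(list(bound = edge, flat = TRUE))
    }
    root <- stats::uniroot(g, lower = min(x_opt[[nm]], edge),
                           upper = max(x_opt[[nm]], edge), tol = 1e-8)
    list(bound = root$root, flat = FALSE)
  }
  rows <- lapply(.param_names, function(nm) {
    lo <- scan_dir(nm, -1); hi <- scan_dir(nm, +1)
    tibble::tibble(parameter = nm, estimate = x_opt[[nm]],
                   lower = lo$bound, upper = hi$bound,
                   flat_lower = lo$flat, flat_upper = hi$flat)
  })
  dplyr::bind_rows(rows)
}
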