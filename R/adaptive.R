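#' Resident equilibrium under density-dependent dynamics
#'
#' Finds the stationary population of a resident strategy `d_res` under
#' the calibrated Ricker density modifier. With `method = "root"` the
#' stationary density solves `lambda(N) = 1` by Brent root-finding (to
#' near machine precision, as the neutrality of invasion fitness
#' requires) and the stationary structure is the dominant right
#' eigenvector at that density. With `method = "iterate"` the
#' density-coupled projection is run from a single founder plant until
#' the density stabilizes, then polished by the same root-finder.
#'
#' @param model A [sprout_model()] with `dd_rate` and `ricker` set.
#' @param d_res Resident sprouting intercept deviation.
#' @param method `"root"` or `"iterate"`.
#' @param founder Optional founder vector (iterate method).
#' @param N_hint Optional starting guess for the stationary density.
#' @return List with `density`, `structure` (scaled so total individuals
#'   = density x area), `lambda` (= 1 at equilibrium) and `converged`.
#' @export
resident_equilibrium <- function(model, d_res = 0,
                                 method = c("root", "iterate"),
                                 founder = NULL, N_hint = NULL) {
  method <- match.arg(method)
  if (is.null(model$ricker) || is.null(model$dd_rate))
    ss_stop("configuration_error", "model needs a calibrated density-dependent rate")
  lam_at <- function(N)
    dominant_lambda(build_annual_matrix(model, d_spr = d_res, density = N))
  it <- NULL
  if (method == "iterate") {
    it <- iterate_density(model, d_spr = d_res, founder = founder)
    if (!it$converged) ss_stop("equilibrium_error", "density iteration did not converge")
    N_hint <- it$density
  }
  if (lam_at(0) <= 1)
    ss_stop("equilibrium_error", "resident not viable at zero density")
  hi <- N_hint %||% (attr(model$ricker, "plateau") %||% 1)
  while (lam_at(hi) > 1) {
    hi <- hi * 2
    if (hi > 1e9) ss_stop("equilibrium_error", "no finite equilibrium density")
  }
  Nstar <- uniroot(function(N) lam_at(N) - 1, c(0, hi),
                   tol = .Machine$double.eps^0.75)$root
  A <- build_annual_matrix(model, d_spr = d_res, density = Nstar)
  et <- eigen_triple(A)
  w <- et$w * Nstar * model$area
  list(density = Nstar, structure = w, lambda = et$lambda,
       converged = TRUE, d_res = d_res,
       trajectory = if (!is.null(it)) it$trajectory else NULL)
}

#' Invasion fitness of a mutant sprouting strategy
#'
#' A single invading mutant (one individual, distributed over states in
#' proportion to the resident's stationary structure) is introduced into
#' the resident's equilibrium and its share of the population projected
#' forward; fitness is the average log growth rate of the mutant share
#' per annual step. In deterministic mode the environment (climate at
#' its mean, density at the resident equilibrium) is constant, so the
#' projection is continued past `steps` until the per-step growth
#' converges; the result equals the log dominant eigenvalue of the
#' mutant matrix in the resident environment (rare-mutant linearity) and
#' is exactly 0 for a neutral mutant. In stochastic mode resident and
#' mutant are projected together for `steps` drawn years (shared climate
#' and year deviations, density set by their combined total) and fitness
#' is the arithmetic mean of the log share growth.
#'
#' @param model A [sprout_model()] with calibrated density dependence.
#' @param d_res Resident deviation.
#' @param d_mut Mutant deviation.
#' @param steps Number of annual steps (default 100).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed Seed for stochastic draws.
#' @param resident Optional precomputed [resident_equilibrium()].
#' @return List with `fitness` (per-step log growth of the mutant
#'   share), `mode`, and `extinct` flag.
#' @export
invasion_fitness <- function(model, d_res, d_mut, steps = 100,
                             mode = c("deterministic", "stochastic"),
                             seed = NULL, resident = NULL) {
  mode <- match.arg(mode)
  if (steps < 1) ss_stop("invalid_argument", "steps must be >= 1")
  res <- resident %||% resident_equilibrium(model, d_res)
  u0 <- res$structure / sum(res$structure)
  if (mode == "deterministic") {
    A <- build_annual_matrix(model, d_spr = d_mut, density = res$density)
    pl <- power_lambda(A, v0 = u0, tol = 1e-14, max_iter = max(steps, 50000))
    if (pl$lambda <= 0) return(list(fitness = -745, mode = mode, extinct = TRUE))
    return(list(fitness = pl$log_lambda, mode = mode, extinct = FALSE,
                resident = res))
  }
  with_seed(seed, {
    vres <- res$structure
    vmut <- u0
    lg <- numeric(steps)
    share <- sum(vmut) / (sum(vmut) + sum(vres))
    for (s in seq_len(steps)) {
      drawn <- draw_stochastic_year(model)
      N <- (sum(vres) + sum(vmut)) / model$area
      Ares <- build_annual_matrix(model, climate = drawn$climate,
                                  d_spr = res$d_res %||% d_res, density = N,
                                  year_dev = as.list(drawn$year_dev))
      Amut <- build_annual_matrix(model, climate = drawn$climate,
                                  d_spr = d_mut, density = N,
                                  year_dev = as.list(drawn$year_dev))
      vres <- as.numeric(Ares %*% vres)
      vmut <- as.numeric(Amut %*% vmut)
      tot <- sum(vres) + sum(vmut)
      share2 <- sum(vmut) / tot
      if (share2 < 1e-300) {
        return(list(fitness = -745, mode = mode, extinct = TRUE))
      }
      lg[s] <- log(share2 / share)
      share <- share2
      ## renormalize to avoid overflow over long runs
      vres <- vres / tot; vmut <- vmut / tot
    }
    list(fitness = mean(lg), mode = mode, extinct = FALSE, resident = res)
  })
}

#' Pairwise invasibility grid
#'
#' Invasion fitness at every (resident, mutant) node of a trait grid.
#' The sign pattern of the grid is the pairwise invasibility plot: the
#' diagonal is neutral (fitness 0 in deterministic mode), and an ESS is
#' a resident column along which no mutant has positive fitness.
#'
#' @param model A [sprout_model()] with calibrated density dependence.
#' @param d_range Range of intercept deviations, default `c(-3, 3)`.
#' @param resolution Number of grid nodes per axis (default 21).
#' @param mode Projection mode.
#' @param steps,seed Passed to [invasion_fitness()].
#' @return A `pip_grid`: list with `d_values` and `fitness` (rows =
#'   resident, columns = mutant; `NA` where the resident has no
#'   equilibrium).
#' @export
pip <- function(model, d_range = c(-3, 3), resolution = 21,
                mode = "deterministic", steps = 100, seed = NULL) {
  dv <- seq(d_range[1], d_range[2], length.out = resolution)
  fit <- matrix(NA_real_, resolution, resolution,
                dimnames = list(resident = sprintf("%.4f", dv),
                                mutant = sprintf("%.4f", dv)))
  for (i in seq_along(dv)) {
    res <- tryCatch(resident_equilibrium(model, dv[i]), error = function(e) NULL)
    if (is.null(res)) next
    for (j in seq_along(dv)) {
      f <- tryCatch(invasion_fitness(model, dv[i], dv[j], steps = steps,
                                     mode = mode, seed = seed, resident = res),
                    error = function(e) NULL)
      if (!is.null(f)) fit[i, j] <- f$fitness
    }
  }
  structure(list(d_values = dv, fitness = fit, mode = mode),
            class = "pip_grid")
}

#' Write a PIP grid as CSV
#'
#' Rows are resident trait values, columns mutant trait values.
#'
#' @param grid A `pip_grid`.
#' @param path File path.
#' @export
write_pip_csv <- function(grid, path) {
  df <- data.frame(resident = grid$d_values, grid$fitness, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## selection gradient at resident d: d fitness(d, m)/dm at m = d
selection_gradient <- function(model, d, h = 1e-3, mode = "deterministic",
                               steps = 100, seed = NULL) {
  res <- resident_equilibrium(model, d)
  fp <- invasion_fitness(model, d, d + h, steps = steps, mode = mode,
                         seed = seed, resident = res)$fitness
  fm <- invasion_fitness(model, d, d - h, steps = steps, mode = mode,
                         seed = seed, resident = res)$fitness
  (fp - fm) / (2 * h)
}

#' Locate the evolutionarily stable sprouting strategy
#'
#' Root-finds the selection gradient
#' `g(d) = d fitness(d, m)/dm |_{m = d}` (central difference, step `h`)
#' over `bounds` by Brent's method. The optimum is classified as
#' convergence-stable when the gradient decreases through zero and as a
#' local fitness maximum when the second derivative of fitness in the
#' mutant direction is negative.
#'
#' @param model A [sprout_model()] with calibrated density dependence.
#' @param bounds Trait bounds bracketing a sign change of the gradient
#'   (default `c(-3, 3)`).
#' @param tol Tolerance on the located deviation.
#' @param h Central-difference step.
#' @param mode Projection mode.
#' @return An `ess_estimate`: list with `d_star`, `gradient`,
#'   `convergence_stable`, `local_max`, `se` (`NA` until bootstrapped).
#' @export
find_ess <- function(model, bounds = c(-3, 3), tol = 1e-4, h = 1e-3,
                     mode = "deterministic") {
  g <- function(d) selection_gradient(model, d, h = h, mode = mode)
  g_at <- function(d) tryCatch(g(d), error = function(e) NA_real_)
  ## shrink bounds inward to the viable resident range (the trait window
  ## where an equilibrium exists) before bracketing
  lo <- bounds[1]; hi <- bounds[2]
  glo <- g_at(lo); ghi <- g_at(hi)
  for (i in 1:14) {
    if (is.finite(glo)) break
    lo <- lo + (hi - lo) * 0.12; glo <- g_at(lo)
  }
  for (i in 1:14) {
    if (is.finite(ghi)) break
    hi <- hi - (hi - lo) * 0.12; ghi <- g_at(hi)
  }
  bounds <- c(lo, hi)
  if (!is.finite(glo) || !is.finite(ghi) || lo >= hi || sign(glo) == sign(ghi))
    ss_stop("no_ess", sprintf("selection gradient does not change sign on [%.3g, %.3g]",
                              bounds[1], bounds[2]))
  root <- uniroot(g, bounds, f.lower = glo, f.upper = ghi, tol = tol)
  d_star <- root$root
  dh <- max(0.05, 10 * tol)
  gp <- (g(min(d_star + dh, bounds[2])) - g(max(d_star - dh, bounds[1]))) /
    (min(d_star + dh, bounds[2]) - max(d_star - dh, bounds[1]))
  res <- resident_equilibrium(model, d_star)
  f0 <- invasion_fitness(model, d_star, d_star, resident = res)$fitness
  fp <- invasion_fitness(model, d_star, d_star + dh, resident = res)$fitness
  fm <- invasion_fitness(model, d_star, d_star - dh, resident = res)$fitness
  curv <- (fp - 2 * f0 + fm) / dh^2
  structure(list(d_star = d_star, gradient = root$f.root,
                 convergence_stable = gp < 0, local_max = curv < 0,
                 curvature = curv, se = NA_real_, bounds = bounds,
                 mode = mode),
            class = "ess_estimate")
}

#' @export
print.ess_estimate <- function(x, ...) {
  cat(sprintf("ESS sprouting-intercept deviation: d* = %.4f%s\n", x$d_star,
              if (is.na(x$se)) "" else sprintf(" +/- %.4f (bootstrap SE)", x$se)))
  cat(sprintf("  convergence-stable: %s; local fitness maximum: %s\n",
              x$convergence_stable, x$local_max))
  invisible(x)
}

#' Bootstrap standard error of the ESS
#'
#' Hierarchical non-parametric bootstrap: individuals are resampled with
#' replacement (all records of an individual move together), the
#' vital-rate models are refit, the Ricker modifier recalibrated and the
#' ESS relocated. The standard error is the standard deviation of the
#' replicate estimates. Replicate-level failures are logged and
#' excluded; more than 20% failures triggers a reliability warning.
#'
#' @param table Life history table (observed data).
#' @param climate A [climate_series()] or `NULL`.
#' @param config A bundle configuration (see [fit_model_bundle()]).
#' @param B Number of bootstrap replicates (the full analysis uses 1000;
#'   the desk-scale default is 100).
#' @param seed Master seed.
#' @param bounds,tol Passed to [find_ess()].
#' @return List with `se`, `estimates`, `n_fail`.
#' @export
bootstrap_ess <- function(table, climate, config, B = 100, seed = 1L,
                          bounds = c(-3, 3), tol = 1e-3) {
  if (B < 2) ss_stop("invalid_argument", "B must be >= 2")
  tab <- as.data.frame(table)
  ids <- unique(tab$id)
  split_tab <- split(tab, tab$id)
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- with_seed(sub_seed(seed, "bootstrap", b),
                      sample(ids, length(ids), replace = TRUE))
    res <- lapply(seq_along(pick), function(i) {
      d <- split_tab[[as.character(pick[i])]]
      d$id <- i  # resampled copies are distinct individuals
      d
    })
    tb <- do.call(rbind, res)
    class(tb) <- class(table)
    attr(tb, "design") <- attr(table, "design")
    est[b] <- tryCatch({
      mb <- fit_model_bundle(tb, climate, config)
      mb$ricker <- calibrate_ricker(mb, config$plateau_target)
      find_ess(mb, bounds = bounds, tol = tol)$d_star
    }, error = function(e) NA_real_)
  }
  nf <- sum(is.na(est))
  if (nf > 0.2 * B) ss_warn("bootstrap_unreliable",
                            sprintf("%d of %d bootstrap replicates failed", nf, B))
  list(se = sd(est, na.rm = TRUE), estimates = est, n_fail = nf)
}
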