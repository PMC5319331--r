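#' Ricker density-modifier parameters
#'
#' The density modifier `alpha - beta * N` is added on the link scale of
#' the selected density-dependent vital rate (logit for probabilities, log
#' for counts), so probabilities remain in `[0, 1]` without clipping and a
#' log-link scalar model reduces exactly to the classic Ricker map
#' `N_{t+1} = N_t exp(alpha - beta N_t)`.
#'
#' @param alpha Intercept of the modifier (dimensionless, link scale).
#' @param beta Per-capita crowding coefficient (per individuals m^-2);
#'   `beta >= 0` for negative density dependence.
#' @param rate Name of the target rate (`"sprouting"` or `"survival"`).
#' @return A `ricker_params` object.
#' @export
ricker_params <- function(alpha, beta, rate = "sprouting") {
  if (beta < 0) ss_stop("invalid_argument", "beta must be >= 0 for negative density dependence")
  structure(list(alpha = alpha, beta = beta, rate = rate),
            class = "ricker_params")
}

#' Apply the Ricker density modifier on the link scale
#'
#' @param value Link-scale value(s) of the target rate.
#' @param N Population density (individuals per square metre).
#' @param params A [ricker_params()].
#' @return Modified link-scale value(s): `value + alpha - beta * N`.
#' @export
apply_density_modifier <- function(value, N, params) {
  value + params$alpha - params$beta * N
}

#' Local density from mapped positions
#'
#' Places a 1 x 1 m (or `cell`-sized) grid over the mapped positions and
#' counts emergent individuals (not sprouts) per cell per year; every
#' individual inherits the count of its own cell, using the half-open
#' assignment rule `[x, x + cell)`.
#'
#' @param table Life history table with `x`, `y` positions.
#' @param cell Grid cell side in metres (default 1).
#' @return The table with a `density` column (individuals per square
#'   metre).
#' @export
local_density <- function(table, cell = 1) {
  tab <- as.data.frame(table)
  if (is.null(tab$x) || is.null(tab$y) || anyNA(tab$x) || anyNA(tab$y))
    ss_stop("missing_data", "positions required for local density")
  cx <- floor(tab$x / cell)
  cy <- floor(tab$y / cell)
  key <- paste(tab$year, cx, cy)
  emerg <- !is.na(tab$sprouted) & tab$sprouted == 1
  counts <- table(key[emerg])
  dens <- as.numeric(counts[key])
  dens[is.na(dens)] <- 0
  tab$density <- dens / cell^2
  class(tab) <- class(table)
  tab
}

#' Screen all vital rates for conspecific density dependence
#'
#' Refits each vital rate with local density added as a fixed term (year
#' effects retained) and classifies the density slope as negative,
#' positive or none by a 2-standard-error rule.
#'
#' @param table Life history table with positions (or a precomputed
#'   `density` column).
#' @param climate A [climate_series()] or `NULL`.
#' @param design `"historical"`, `"agestage"` or `"simple"`.
#' @param rates Named list giving, per response, the character vector of
#'   base terms (density is appended automatically).
#' @param cell Grid cell size for [local_density()].
#' @return A `density_screen` data frame: rate, slope, SE, classification.
#' @export
screen_density <- function(table, climate = NULL, design = "simple",
                           rates = list(survival = character(),
                                        sprouting = character(),
                                        flowering = character()),
                           cell = 1) {
  tab <- as.data.frame(table)
  if (is.null(tab$density)) tab <- local_density(table, cell)
  out <- lapply(names(rates), function(r) {
    res <- tryCatch({
      des <- build_design(tab, climate, design, r)
      fit <- fit_vital_rate(des, c(rates[[r]], "density"),
                            family = resp_defs[[r]]$family)
      if (!fit$converged) ss_stop("fit_error", "non-converged")
      b <- fit$spec$coef[["density"]]
      se <- fit$coef_se[["density"]]
      cls <- if (b + 2 * se < 0) "negative" else if (b - 2 * se > 0) "positive" else "none"
      data.frame(rate = r, slope = b, se = se, classification = cls,
                 converged = TRUE)
    }, error = function(e) data.frame(rate = r, slope = NA_real_,
                                      se = NA_real_,
                                      classification = "non-converged",
                                      converged = FALSE))
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("density_screen", "data.frame")
  res
}

## density-coupled iteration from a founder; returns trajectory & final state
iterate_density <- function(model, d_spr = 0, founder = NULL, max_steps = 5000,
                            rel_tol = 1e-6, consec = 50) {
  space <- model$space
  if (is.null(founder)) {
    ## a single plant in the first adult entry state
    entry <- space$entry_stages[which(space$entry_stages != "D")[1]]
    eidx <- which(space$states$class_cur == "adult" &
                    !is.na(space$states$cur_stage) &
                    space$stage_tab$name[space$states$cur_stage] == entry)[1]
    founder <- rep(0, space$n)
    founder[eidx] <- 1
  }
  v <- founder
  N <- sum(v) / model$area
  hist <- numeric(0)
  stable <- 0
  for (i in seq_len(max_steps)) {
    A <- build_annual_matrix(model, d_spr = d_spr, density = N)
    v <- as.numeric(A %*% v)
    N2 <- sum(v) / model$area
    hist[i] <- N2
    if (N2 <= 0) break
    if (abs(N2 - N) <= rel_tol * max(N, 1e-12)) stable <- stable + 1 else stable <- 0
    N <- N2
    if (stable >= consec) {
      return(list(density = N, structure = v, trajectory = hist,
                  converged = TRUE, steps = i))
    }
  }
  list(density = N, structure = v, trajectory = hist, converged = FALSE,
       steps = length(hist))
}

## lambda of the annual matrix with a raw link offset c applied to the
## density-dependent rate (alpha = c, beta = 0, N = 0)
lambda_at_offset <- function(model, cval, d_spr = 0) {
  m <- model
  m$ricker <- ricker_params(cval, 0, m$dd_rate %||% "sprouting")
  dominant_lambda(build_annual_matrix(m, d_spr = d_spr, density = 0))
}

#' Calibrate the Ricker density modifier to a plateau density
#'
#' Finds `(alpha, beta)` such that the density-coupled projection from a
#' single founder plant converges to a stationary density within
#' tolerance of `plateau_target`. The calibration profiles `alpha`
#' exactly: the link offset `c*` at which the modified annual matrix has
#' dominant eigenvalue 1 is root-found, and `alpha = c* + beta *
#' plateau_target`, so the stationary density equals the target for any
#' stable `beta`; `beta` is then reduced from its initial scale until the
#' coupled iteration converges stably.
#'
#' @param model A [sprout_model()] with `dd_rate` set (or supplied here).
#' @param plateau_target Target stationary density (individuals per
#'   square metre), > 0.
#' @param rate Density-dependent rate; defaults to `model$dd_rate`.
#' @param tol Relative tolerance on the achieved plateau (default 2%).
#' @param beta_init Initial crowding coefficient; default `|c*| /
#'   plateau_target`.
#' @return A [ricker_params()] with attribute `plateau` (the achieved
#'   stationary density).
#' @export
calibrate_ricker <- function(model, plateau_target, rate = NULL, tol = 0.02,
                             beta_init = NULL) {
  if (plateau_target <= 0) ss_stop("invalid_argument", "plateau_target must be > 0")
  rate <- rate %||% model$dd_rate
  if (is.null(rate)) ss_stop("configuration_error", "no density-dependent rate selected")
  model$dd_rate <- rate
  lam0 <- lambda_at_offset(model, 0)
  if (lam0 <= 1)
    ss_stop("calibration_failure",
            sprintf("no asymptotic growth at zero density (lambda = %.4f)", lam0))
  ## scan downward for the first crossing of lambda = 1 (stable root:
  ## lambda increasing in the offset there)
  lo <- -0.5
  while (lambda_at_offset(model, lo) > 1) {
    lo <- lo - 0.5
    if (lo < -40) ss_stop("calibration_failure", "rate modifier cannot bring lambda to 1")
  }
  cstar <- uniroot(function(cv) lambda_at_offset(model, cv) - 1,
                   c(lo, lo + 0.5), tol = 1e-10)$root
  beta <- beta_init %||% (max(abs(cstar), 0.1) / plateau_target)
  for (try in 1:15) {
    rp <- ricker_params(cstar + beta * plateau_target, beta, rate)
    model$ricker <- rp
    it <- iterate_density(model)
    if (it$converged && abs(it$density - plateau_target) <= tol * plateau_target) {
      attr(rp, "plateau") <- it$density
      attr(rp, "c_star") <- cstar
      return(rp)
    }
    beta <- beta / 2
  }
  ss_stop("calibration_failure", "no stable (alpha, beta) found in bounds")
}

#' Select the density-dependent vital rate
#'
#' Among rates screened as negatively density-dependent, returns the
#' first (in a documented priority order: sprouting, survival, flowering,
#' growth) for which Ricker calibration to the target plateau succeeds.
#'
#' @param screen A `density_screen` from [screen_density()].
#' @param model A [sprout_model()].
#' @param plateau_target Target plateau density.
#' @param priority Priority order over rate names.
#' @return The selected rate name, with the calibrated [ricker_params()]
#'   as attribute `ricker`.
#' @export
select_dd_rate <- function(screen, model, plateau_target,
                           priority = c("sprouting", "survival", "flowering",
                                        "growth")) {
  neg <- screen$rate[screen$classification == "negative"]
  cand <- priority[priority %in% neg]
  for (r in cand) {
    rp <- tryCatch(calibrate_ricker(model, plateau_target, rate = r),
                   error = function(e) NULL)
    if (!is.null(rp)) {
      out <- r
      attr(out, "ricker") <- rp
      return(out)
    }
  }
  ss_stop("selection_failure", "no negatively density-dependent rate yields a stable plateau")
}
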