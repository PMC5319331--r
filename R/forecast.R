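#' Per-year optimal sprouting trajectory under a climate series
#'
#' For each requested year the deterministic climate input is set to the
#' mean of that year and the preceding `window` years (26 values with the
#' default window), and the ESS sprouting deviation is relocated. Each
#' year therefore has its own optimum, tracking the climate the
#' optimizing selection would have integrated over. Adjacent years reuse
#' the previous optimum as a warm start (narrowed bracket, widened back
#' to `bounds` if it fails). Years whose gradient does not bracket a
#' root are recorded as missing, not interpolated.
#'
#' @param model A [sprout_model()] with calibrated density dependence.
#'   Climate covariates in the specs must be named `<var>` matching the
#'   series columns (deterministic builds read them from
#'   `climate_spec$mean`).
#' @param climate A [climate_series()] long enough for at least one full
#'   window.
#' @param years Years to optimize (default: all with a full window).
#' @param window Number of preceding years in the running mean.
#' @param bounds,tol Passed to [find_ess()].
#' @return An `evolution_trajectory` data frame: `year`, `d_star`,
#'   `converged`.
#' @export
optimal_trajectory <- function(model, climate, years = NULL, window = 25,
                               bounds = c(-3, 3), tol = 1e-3) {
  rm <- running_mean_inputs(climate, window)
  years <- years %||% rm$year
  if (!all(years %in% rm$year))
    ss_stop("invalid_argument", "running-mean inputs unavailable for some requested years")
  vars <- setdiff(names(rm), "year")
  d_prev <- NA_real_
  out <- data.frame(year = years, d_star = NA_real_, converged = FALSE)
  for (i in seq_along(years)) {
    vals <- unlist(rm[rm$year == years[i], vars, drop = FALSE])
    names(vals) <- vars
    m <- set_model_climate(model, expand_climate_values(model, as.list(vals)))
    est <- NULL
    if (is.finite(d_prev)) {
      bb <- c(max(bounds[1], d_prev - 0.5), min(bounds[2], d_prev + 0.5))
      est <- tryCatch(find_ess(m, bounds = bb, tol = tol), error = function(e) NULL)
    }
    if (is.null(est))
      est <- tryCatch(find_ess(m, bounds = bounds, tol = tol), error = function(e) NULL)
    if (!is.null(est)) {
      out$d_star[i] <- est$d_star
      out$converged[i] <- TRUE
      d_prev <- est$d_star
    } else d_prev <- NA_real_
  }
  class(out) <- c("evolution_trajectory", "data.frame")
  out
}

#' Annual deterministic growth rates with and without trait evolution
#'
#' For each year an annual matrix is built at that year's climate values
#' (annual values, not running means) with the sprouting deviation set to
#' the evolved optimum `d*(Y)` and to 0, and the deterministic growth
#' rate is taken as the dominant eigenvalue. No density modifier is
#' applied: these are asymptotic annual rates.
#'
#' @param model A [sprout_model()].
#' @param climate A [climate_series()].
#' @param trajectory An `evolution_trajectory` (or `NULL` for static
#'   only).
#' @param years Years to evaluate (default: trajectory years, else all
#'   climate years).
#' @return A `lambda_series` data frame: `year`, `lambda_evolved`,
#'   `lambda_static`.
#' @export
lambda_series <- function(model, climate, trajectory = NULL, years = NULL) {
  years <- years %||% (if (!is.null(trajectory)) trajectory$year else climate$year)
  vars <- climate_vars(climate)
  m_nd <- model
  m_nd$ricker <- NULL; m_nd$dd_rate <- NULL
  out <- data.frame(year = years, lambda_evolved = NA_real_,
                    lambda_static = NA_real_)
  for (i in seq_along(years)) {
    row <- climate[climate$year == years[i], , drop = FALSE]
    if (nrow(row) == 0) ss_stop("missing_data", sprintf("no climate for year %s", years[i]))
    vals <- unlist(row[vars]); names(vals) <- vars
    vals <- expand_climate_values(m_nd, as.list(vals))
    d <- 0
    if (!is.null(trajectory)) {
      j <- match(years[i], trajectory$year)
      if (!is.na(j) && is.finite(trajectory$d_star[j])) d <- trajectory$d_star[j]
    }
    A0 <- build_annual_matrix(m_nd, climate = vals, d_spr = 0)
    out$lambda_static[i] <- dominant_lambda(A0)
    out$lambda_evolved[i] <- if (d == 0) out$lambda_static[i] else
      dominant_lambda(build_annual_matrix(m_nd, climate = vals, d_spr = d))
  }
  class(out) <- c("lambda_series", "data.frame")
  out
}

## classify each admissible transition for LTRE category sums
transition_category <- function(space, row, col) {
  st <- space$states
  if (row == space$fec_to && st$flw_cur[col] == 1 &&
      !is.na(st$cur_stage[col])) return("fecundity")
  if (is.na(st$cur_stage[col])) return("juvenile")
  sz_from <- st$size_cur[col]; sz_to <- st$size_cur[row]
  cls <- if (st$size_cur[row] == 0) "dormancy" else
    if (st$flw_cur[row] == 1) "flowering" else "vegetative"
  mov <- if (sz_to > sz_from) "growth" else if (sz_to < sz_from) {
    if (sz_to == 0 && sz_from == 0) "stasis" else "shrinkage"
  } else "stasis"
  if (sz_to == 0 && sz_from == 0) mov <- "stasis"
  paste(mov, cls, sep = "-")
}

#' Life table response experiment between two matrices
#'
#' Fixed-design LTRE: the growth-rate difference between an evolved and
#' a static matrix is decomposed into per-element contributions
#' `C = (A_evolved - A_static) * sensitivity(A_mid)`, where `A_mid` is
#' the element-wise mean matrix and the sensitivity of the dominant
#' eigenvalue is computed from its eigen-triple
#' (`s_ij = v_i w_j / <v, w>`). The sum of contributions approximates
#' `lambda(evolved) - lambda(static)` to first order. When a state space
#' is supplied, contributions are also summed by transition category
#' (stasis/growth/shrinkage crossed with dormancy/vegetative/flowering
#' targets, plus fecundity and juvenile arcs).
#'
#' @param A_evolved,A_static Square matrices on the same state space.
#' @param space Optional `state_space` for category sums.
#' @return An `ltre_result`: list with `contributions`, `total`,
#'   `delta_lambda`, `categories` (data frame or `NULL`).
#' @export
ltre <- function(A_evolved, A_static, space = NULL) {
  if (!all(dim(A_evolved) == dim(A_static)))
    ss_stop("invalid_argument", "matrices must have identical dimensions")
  A_mid <- (unclass(A_evolved) + unclass(A_static)) / 2
  et <- eigen_triple(A_mid)
  sens <- outer(et$v, et$w)
  C <- (unclass(A_evolved) - unclass(A_static)) * sens
  dl <- dominant_lambda(A_evolved) - dominant_lambda(A_static)
  cats <- NULL
  if (!is.null(space)) {
    nz <- which(C != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      lab <- vapply(seq_len(nrow(nz)), function(i)
        transition_category(space, nz[i, 1], nz[i, 2]), character(1))
      agg <- tapply(C[nz], lab, sum)
      cats <- data.frame(category = names(agg), contribution = as.numeric(agg))
      cats <- cats[order(-abs(cats$contribution)), , drop = FALSE]
      rownames(cats) <- NULL
    }
  }
  structure(list(contributions = C, total = sum(C), delta_lambda = dl,
                 categories = cats),
            class = "ltre_result")
}

#' @export
print.ltre_result <- function(x, ...) {
  cat(sprintf("LTRE: delta lambda = %.6f, sum of contributions = %.6f\n",
              x$delta_lambda, x$total))
  if (!is.null(x$categories)) print(head(x$categories, 10))
  invisible(x)
}
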