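#' Fecundity and juvenile-pathway parameters
#'
#' Juvenile stages are not monitored in the field; their rates are
#' literature-derived configuration, not fitted constants. The fecundity
#' chain is: expected flowers per flowering plant (from the flower-count
#' model, or `flowers_const`), times fruiting probability (fruiting model
#' or `fruit_set`), times fruits per fruiting plant (fruit-count model or
#' the flower count itself), times `seeds_per_fruit`, times `germination`,
#' entering the first juvenile state the following year.
#'
#' @param seeds_per_fruit Seeds per fruit (count).
#' @param germination Fraction of seeds germinating to the first juvenile
#'   state.
#' @param fruit_set Fruiting probability used when no fruiting model is
#'   supplied.
#' @param flowers_const Expected flowers per flowering plant used when no
#'   flower-count model is supplied.
#' @param juvenile Named list of juvenile-pathway parameters:
#'   per-stage survival/transition probabilities (`s_protocorm1`,
#'   `s_protocorm2`, `s_protocorm3`, `s_newseedling`, `s_seedling`),
#'   the juvenile sprouting probability `q_juv` (modified on the logit
#'   scale by the density modifier when sprouting is the selected
#'   density-dependent rate; the evolving adult deviation `d_spr` does
#'   not apply to juveniles), `sprout_weights` (relative weights of 1 vs
#'   2 sprouts at seedling emergence) and `entry_weights` (relative
#'   weights of the emergent adult entry stages).
#' @return A `fecundity_params` object.
#' @export
fecundity_params <- function(seeds_per_fruit = 5000, germination = 5e-4,
                             fruit_set = 0.5, flowers_const = 1,
                             juvenile = list()) {
  juv <- utils::modifyList(list(
    s_protocorm1 = 0.4, s_protocorm2 = 0.45, s_protocorm3 = 0.45,
    s_newseedling = 0.45, s_seedling = 0.4, q_juv = 0.5,
    sprout_weights = c(0.7, 0.3), entry_weights = NULL), juvenile)
  p <- list(seeds_per_fruit = seeds_per_fruit, germination = germination,
            fruit_set = fruit_set, flowers_const = flowers_const,
            juvenile = juv)
  frac <- c(p$germination, p$fruit_set,
            unlist(juv[grep("^s_|^q_", names(juv))]))
  if (any(frac < 0 | frac > 1)) ss_stop("invalid_argument", "fractions must lie in [0,1]")
  if (seeds_per_fruit < 0) ss_stop("invalid_argument", "counts must be >= 0")
  structure(p, class = "fecundity_params")
}

#' Perturb fecundity parameters
#'
#' Scales chosen juvenile/fecundity parameters by `1 + factor` for the
#' sensitivity harness that checks ESS stability under juvenile-parameter
#' uncertainty (the conventional perturbation is +/- 10%). Fractions that
#' would exceed 1 are clipped with a warning. Note the perturbation is
#' multiplicative, so -10% followed by +10% is not the identity (0.99x).
#'
#' @param params A [fecundity_params()].
#' @param factor Relative change (e.g. `0.1` or `-0.1`).
#' @param fields Character vector of fields to scale; juvenile fields are
#'   addressed as `"juvenile.s_seedling"` etc.
#' @return A scaled copy of `params`.
#' @export
perturb_fecundity <- function(params, factor,
                              fields = c("seeds_per_fruit", "germination",
                                         "juvenile.s_seedling")) {
  p <- params
  for (f in fields) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      v <- p[[f]] * (1 + factor)
      if (f %in% c("germination", "fruit_set") && v > 1) {
        ss_warn("clipped_fraction", sprintf("%s clipped to 1", f)); v <- 1
      }
      p[[f]] <- v
    } else {
      v <- p[[parts[1]]][[parts[2]]] * (1 + factor)
      if (grepl("^s_|^q_", parts[2]) && v > 1) {
        ss_warn("clipped_fraction", sprintf("%s clipped to 1", f)); v <- 1
      }
      p[[parts[1]]][[parts[2]]] <- v
    }
  }
  p
}

#' Assemble a demographic model bundle
#'
#' Binds together everything needed to build annual projection matrices:
#' a state space, the per-rate vital-rate specs, fecundity/juvenile
#' parameters, the climate covariate distribution (means and standard
#' deviations on the scales the specs use), the plot area over which
#' density is measured, and optionally the selected density-dependent rate
#' with its calibrated Ricker parameters.
#'
#' @param space A `state_space`.
#' @param specs Named list of [vr_spec()] objects: `survival`, `sprouting`,
#'   `growth`, `flowering` required; `flowercount`, `fruiting`,
#'   `fruitcount` optional.
#' @param fec A [fecundity_params()].
#' @param climate_spec List with named numeric vectors `mean` and `sd`
#'   over the climate covariates the specs reference.
#' @param area Plot area in square metres (density = individuals / area).
#' @param dd_rate `"sprouting"`, `"survival"` or `NULL` (no density
#'   dependence configured).
#' @param ricker Optional [ricker_params()].
#' @param year_table Optional data frame (`year`, one column per rate)
#'   of fitted year deviations, plus matching climate columns, used by the
#'   stochastic mode to resample whole years.
#' @return A `sprout_model` object.
#' @export
sprout_model <- function(space, specs, fec = fecundity_params(),
                         climate_spec = list(mean = numeric(), sd = numeric()),
                         area = 100, dd_rate = NULL, ricker = NULL,
                         year_table = NULL) {
  need <- c("survival", "sprouting", "growth", "flowering")
  miss <- setdiff(need, names(specs))
  if (length(miss)) ss_stop("configuration_error",
                            paste("missing vital-rate specs:", paste(miss, collapse = ", ")))
  structure(list(space = space, specs = specs, fec = fec,
                 climate_spec = climate_spec, area = area,
                 dd_rate = dd_rate, ricker = ricker, year_table = year_table),
            class = "sprout_model")
}

#' @export
print.sprout_model <- function(x, ...) {
  cat(sprintf("demographic model bundle: %s space (%d states), rates: %s\n",
              x$space$design, x$space$n, paste(names(x$specs), collapse = ", ")))
  if (!is.null(x$dd_rate)) cat("  density-dependent rate:", x$dd_rate, "\n")
  invisible(x)
}

## replace the deterministic climate means (used by per-year forecasting)
set_model_climate <- function(model, values) {
  v <- unlist(values)
  model$climate_spec$mean[names(v)] <- v
  model
}

#' Truncated-Poisson growth distribution
#'
#' The size distribution conditional on survival and sprouting: a Poisson
#' pmf with the model's mean, truncated to `{1..max_size}` (dormancy is
#' carried by the sprouting probability, not by the growth distribution)
#' and renormalized to sum to one.
#'
#' @param size_spec Poisson-log [vr_spec()] for size.
#' @param cov Covariate data frame (one row per source state).
#' @param max_size Maximum size class.
#' @param year_dev Link-scale year deviation.
#' @return Matrix with one row per covariate row and `max_size` columns,
#'   each row summing to 1.
#' @export
growth_distribution <- function(size_spec, cov, max_size, year_dev = 0) {
  if (max_size < 1) ss_stop("invalid_argument", "max_size must be >= 1")
  if (size_spec$family != "poisson")
    ss_stop("invalid_argument", "size spec must be Poisson/log")
  mu <- eval_rate(size_spec, cov, year_dev)
  g <- outer(mu, seq_len(max_size), function(l, k) dpois(k, l))
  s <- rowSums(g)
  zero <- s <= 0
  if (any(zero)) { g[zero, ] <- 0; g[zero, 1] <- 1; s[zero] <- 1 }
  g / s
}

#' Transition-entry kernel
#'
#' The three transition probabilities out of a surviving individual:
#' dormancy `a_D = S (1 - P)`; vegetative arrival in size k
#' `a_k(V) = S P g_k (1 - F_k)`; flowering arrival in size k
#' `a_k(F) = S P g_k F_k`. Given `sum_k g_k = 1` these satisfy
#' `a_D + sum_k (a_k(V) + a_k(F)) = S` exactly.
#'
#' @param S Survival probability (scalar or vector).
#' @param P Sprouting probability conditional on survival.
#' @param g Growth distribution over target sizes (vector or matrix with
#'   rows matching `S`).
#' @param F_k Flowering probability per target size (same shape as `g`).
#' @return List with elements `aD`, `aV`, `aF`.
#' @export
transition_entries <- function(S, P, g, F_k) {
  list(aD = S * (1 - P), aV = S * P * g * (1 - F_k), aF = S * P * g * F_k)
}

ricker_offset <- function(ricker, density) {
  if (is.null(ricker) || is.null(density)) return(0)
  apply_density_modifier(0, density, ricker)
}

#' Build an annual projection matrix
#'
#' Fills every admissible arc of the state space from the vital-rate
#' functions: adult columns through the transition kernel
#' (survival x sprouting x growth x flowering), juvenile columns from the
#' configured juvenile pathway, and fecundity arcs from flowering states
#' to the first juvenile state. Matrices are column-to-row oriented: the
#' column is the source state.
#'
#' In deterministic mode climate covariates default to their configured
#' means and year deviations are zero. In stochastic mode a year is drawn:
#' if the bundle carries a fitted `year_table`, a monitored year is
#' resampled together with its per-rate deviations and climate values;
#' otherwise deviations are drawn from each rate's year-effect standard
#' deviation and climate values from their configured normal
#' distributions.
#'
#' @param model A [sprout_model()].
#' @param climate Named list/vector of climate covariate values for the
#'   year (overrides means/draws).
#' @param d_spr Sprouting intercept deviation applied to the adult
#'   sprouting model (the evolving trait).
#' @param density Population density (individuals per square metre) fed to
#'   the Ricker modifier of the selected density-dependent rate; `NULL`
#'   disables density modification.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed Seed for stochastic draws.
#' @param year_dev Optional named list of per-rate link-scale year
#'   deviations (overrides drawing).
#' @return The annual projection matrix with attribute `context`.
#' @export
build_annual_matrix <- function(model, climate = NULL, d_spr = 0,
                                density = NULL,
                                mode = c("deterministic", "stochastic"),
                                seed = NULL, year_dev = NULL) {
  mode <- match.arg(mode)
  space <- model$space
  specs <- model$specs
  fec <- model$fec
  rates <- names(specs)

  clim <- model$climate_spec$mean
  yd <- setNames(rep(0, length(rates)), rates)
  if (mode == "stochastic" && is.null(year_dev)) {
    drawn <- with_seed(seed, draw_stochastic_year(model))
    clim[names(drawn$climate)] <- drawn$climate
    yd[names(drawn$year_dev)] <- drawn$year_dev
  }
  if (!is.null(year_dev)) yd[names(year_dev)] <- unlist(year_dev)
  if (!is.null(climate)) { v <- unlist(climate); clim[names(v)] <- v }

  sc <- state_covariates(space)
  ad <- sc$idx
  cov <- sc$cov
  for (v in names(clim)) cov[[v]] <- clim[[v]]
  cov$density <- if (is.null(density)) 0 else density

  dd_off <- if (!is.null(model$dd_rate)) ricker_offset(model$ricker, density) else 0
  off_surv <- if (identical(model$dd_rate, "survival")) dd_off else 0
  off_spr <- if (identical(model$dd_rate, "sprouting")) dd_off else 0

  S <- eval_rate(specs$survival, cov, yd[["survival"]], offset = off_surv)
  P <- eval_rate(specs$sprouting, cov, yd[["sprouting"]], d_spr = d_spr,
                 offset = off_spr)
  m <- space$max_size
  G <- growth_distribution(specs$growth, cov, m, yd[["growth"]])
  Fk <- matrix(0, length(ad), m)
  for (k in seq_len(m)) {
    ck <- cov; ck$siz_target <- k
    Fk[, k] <- eval_rate(specs$flowering, ck, yd[["flowering"]])
  }

  A <- matrix(0, space$n, space$n)
  ## dormancy target (stage 1)
  A[cbind(space$target[ad, 1], ad)] <- S * (1 - P)
  for (k in seq_len(m)) {
    A[cbind(space$target[ad, 1 + k], ad)] <- S * P * G[, k] * (1 - Fk[, k])
    A[cbind(space$target[ad, 1 + m + k], ad)] <- S * P * G[, k] * Fk[, k]
  }

  ## juvenile pathway
  juv <- fec$juvenile
  q <- plogis(qlogis(juv$q_juv) + off_spr)
  sw <- juv$sprout_weights / sum(juv$sprout_weights)
  em <- setdiff(space$entry_stages, "D")
  ew <- juv$entry_weights %||% setNames(rep(1, length(em)), em)
  ew <- ew[em] / sum(ew[em])
  arcs <- space$juv_arcs
  if (isTRUE(juv$seedling_stasis) && !is.null(arcs) && nrow(arcs)) {
    ## unsprouted seedlings remain seedlings (stasis loop) instead of
    ## entering the dormant adult stage
    redo <- arcs$branch == "D" & arcs$surv == "s_seedling"
    arcs$to[redo] <- arcs$from[redo]
  }
  if (!is.null(arcs) && nrow(arcs)) {
    bp <- vapply(arcs$branch, function(b) {
      if (b == "none") 1
      else if (b == "sprout0") 1 - q
      else if (b == "sprout1") q * sw[1]
      else if (b == "sprout2") q * sw[2]
      else if (b == "D") 1 - q
      else q * ew[[b]]
    }, numeric(1))
    sv <- vapply(arcs$surv, function(s) juv[[s]], numeric(1))
    A[cbind(arcs$to, arcs$from)] <- A[cbind(arcs$to, arcs$from)] + sv * bp
  }

  ## fecundity from flowering states (adult-current only)
  flw <- which(space$states$flw_cur[ad] == 1)
  if (length(flw)) {
    cf <- cov[flw, , drop = FALSE]
    cf$siz_target <- cf$siz_t
    flowers <- if (!is.null(specs$flowercount))
      eval_rate(specs$flowercount, cf, yd[["flowercount"]] %||% 0)
    else rep(fec$flowers_const, length(flw))
    cf$flw_t <- flowers
    fp <- if (!is.null(specs$fruiting))
      eval_rate(specs$fruiting, cf, yd[["fruiting"]] %||% 0)
    else rep(fec$fruit_set, length(flw))
    fc <- if (!is.null(specs$fruitcount))
      eval_rate(specs$fruitcount, cf, yd[["fruitcount"]] %||% 0)
    else flowers
    recruits <- fp * fc * fec$seeds_per_fruit * fec$germination
    src <- ad[flw]
    A[space$fec_to, src] <- A[space$fec_to, src] + recruits
  }

  if (any(!is.finite(A))) ss_stop("numeric_error", "non-finite matrix entries")
  attr(A, "context") <- list(climate = clim, d_spr = d_spr, density = density,
                             mode = mode, seed = seed, year_dev = yd)
  A
}

## draw a stochastic year: resample a monitored year (deviations + climate)
## if a fitted year table exists, else draw from configured distributions
draw_stochastic_year <- function(model) {
  yt <- model$year_table
  if (!is.null(yt) && nrow(yt)) {
    i <- sample.int(nrow(yt), 1)
    rate_cols <- intersect(names(model$specs), names(yt))
    clim_cols <- intersect(names(model$climate_spec$mean), names(yt))
    list(year_dev = unlist(yt[i, rate_cols, drop = FALSE]),
         climate = unlist(yt[i, clim_cols, drop = FALSE]))
  } else {
    sds <- vapply(model$specs, function(s) s$year_sd, numeric(1))
    ydev <- rnorm(length(sds), 0, sds)
    names(ydev) <- names(model$specs)
    cs <- model$climate_spec
    clim <- rnorm(length(cs$mean), cs$mean, cs$sd[names(cs$mean)] %||% 0)
    names(clim) <- names(cs$mean)
    list(year_dev = ydev, climate = clim)
  }
}

#' Dominant eigenvalue of a projection matrix
#'
#' The asymptotic population growth rate: the spectral radius of the
#' non-negative annual matrix, computed by eigen-decomposition.
#'
#' @param A Square non-negative matrix.
#' @return The dominant eigenvalue (real, >= 0).
#' @export
dominant_lambda <- function(A) {
  if (any(!is.finite(A))) ss_stop("numeric_error", "non-finite matrix entries")
  ev <- eigen(A, only.values = TRUE)$values
  max(Re(ev))
}

#' Asymptotic growth rate by power iteration
#'
#' Projects a population vector until the per-step log growth converges;
#' used as an independent cross-check of [dominant_lambda()] and as the
#' simulation route for deterministic invasion fitness.
#'
#' @param A Square non-negative matrix.
#' @param v0 Starting vector (default uniform).
#' @param tol Convergence tolerance on successive log growth rates.
#' @param max_iter Iteration cap.
#' @return List with `lambda`, `log_lambda`, `iterations`, `converged`,
#'   and the normalized stable structure `w`.
#' @export
power_lambda <- function(A, v0 = NULL, tol = 1e-13, max_iter = 200000) {
  n <- nrow(A)
  v <- v0 %||% rep(1 / n, n)
  v <- v / sum(v)
  r_old <- Inf
  for (i in seq_len(max_iter)) {
    v2 <- A %*% v
    s <- sum(v2)
    if (s <= 0) return(list(lambda = 0, log_lambda = -Inf, iterations = i,
                            converged = TRUE, w = v))
    r <- log(s)
    v <- as.numeric(v2 / s)
    if (abs(r - r_old) < tol) {
      return(list(lambda = exp(r), log_lambda = r, iterations = i,
                  converged = TRUE, w = v))
    }
    r_old <- r
  }
  list(lambda = exp(r_old), log_lambda = r_old, iterations = max_iter,
       converged = FALSE, w = v)
}

## dominant eigen-triple (lambda, right vector w, left vector v),
## normalized so sum(w) = 1 and v.w = 1
eigen_triple <- function(A) {
  er <- eigen(A)
  i <- which.max(Re(er$values))
  w <- Re(er$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  el <- eigen(t(A))
  j <- which.max(Re(el$values))
  v <- Re(el$vectors[, j])
  if (sum(v * w) < 0) v <- -v
  v <- v / sum(v * w)
  list(lambda = Re(er$values[i]), w = w, v = v)
}

#' Export/import a projection matrix in MatrixMarket form
#'
#' Writes the matrix as a sparse `.mtx` file plus a sidecar CSV state
#' index (same basename, `.index.csv`) naming every state.
#'
#' @param A Projection matrix.
#' @param space The `state_space` it was built on.
#' @param path Path to the `.mtx` file.
#' @return `read_matrix_mtx` returns the dense matrix.
#' @export
write_matrix_mtx <- function(A, space, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(unclass(A), sparse = TRUE), "generalMatrix"), path)
  write_state_index(space, sub("\\.mtx$", ".index.csv", path))
  invisible(path)
}

#' @rdname write_matrix_mtx
#' @export
read_matrix_mtx <- function(path) as.matrix(Matrix::readMM(path))
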