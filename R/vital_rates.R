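#' Declare a vital-rate model specification
#'
#' A vital-rate spec is the functional form of one demographic rate:
#' a binomial-logit or Poisson-log linear predictor over covariates such
#' as size and flowering status in years t and t-1, growth, age, climate
#' covariates and local density, plus a per-year deviation table with its
#' standard deviation, and (for sprouting models only) the additive
#' intercept deviation `d_spr` that is the evolving trait in the
#' adaptive-dynamics analysis.
#'
#' Terms are covariate names; two-way interactions are written `"a:b"`.
#' The coefficient vector must contain `"(Intercept)"` plus exactly one
#' coefficient per term.
#'
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param terms Character vector of terms (possibly empty).
#' @param coef Named numeric vector: `"(Intercept)"` plus one entry per term.
#' @param year_effects Named numeric vector of per-year link-scale
#'   deviations (names are years); default empty.
#' @param year_sd Standard deviation of the year effect (link scale).
#' @param d_spr Stored intercept deviation (sprouting models; default 0).
#' @return A `vr_spec` object.
#' @export
vr_spec <- function(family = c("binomial", "poisson"), terms = character(),
                    coef, year_effects = numeric(), year_sd = 0, d_spr = 0) {
  family <- match.arg(family)
  terms <- as.character(terms)
  need <- c("(Intercept)", terms)
  if (!setequal(names(coef), need) || length(coef) != length(need))
    ss_stop("invalid_argument",
            "coef must have '(Intercept)' plus exactly one coefficient per term")
  if (year_sd < 0) ss_stop("invalid_argument", "year_sd must be >= 0")
  structure(list(family = family,
                 link = if (family == "binomial") "logit" else "log",
                 terms = terms, coef = coef[need],
                 year_effects = year_effects, year_sd = year_sd,
                 d_spr = d_spr),
            class = "vr_spec")
}

## covariates needed by a term vector
terms_covariates <- function(terms) unique(unlist(strsplit(terms, ":", fixed = TRUE)))

## evaluate term columns for a covariate data frame/list
term_value <- function(term, cov) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  v <- 1
  for (p in parts) {
    if (is.null(cov[[p]])) ss_stop("missing_covariate", sprintf("missing covariate '%s'", p))
    v <- v * cov[[p]]
  }
  v
}

#' Evaluate a vital-rate spec
#'
#' Computes `linkinv(x0 + d_spr + sum(x_term * term) + year_dev + offset)`.
#' Binomial results lie in `[0, 1]`; Poisson results are positive means.
#'
#' @param spec A [vr_spec()].
#' @param cov Named list or data frame of covariate values (vectors allowed).
#' @param year_dev Link-scale year deviation (scalar or vector).
#' @param d_spr Override for the spec's stored intercept deviation; `NULL`
#'   uses `spec$d_spr`.
#' @param offset Additional link-scale offset (used by the density
#'   modifier); default 0.
#' @return Numeric vector of rates.
#' @export
eval_rate <- function(spec, cov, year_dev = 0, d_spr = NULL, offset = 0) {
  d <- if (is.null(d_spr)) spec$d_spr else d_spr
  lp <- spec$coef[["(Intercept)"]] + d + year_dev + offset
  for (tm in spec$terms) lp <- lp + spec$coef[[tm]] * term_value(tm, cov)
  ## one value per covariate row, even for intercept-only specs
  n <- if (is.data.frame(cov)) nrow(cov)
  else if (length(cov)) max(lengths(cov)) else length(lp)
  if (length(lp) == 1 && n > 1) lp <- rep.int(lp, n)
  if (spec$family == "binomial") plogis(lp) else exp(lp)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Parameter count.
#' @param n Observation count.
#' @return AICc value (`Inf` when `n <= k + 1`).
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## ---------------------------------------------------------------------------
## design building

resp_defs <- list(
  survival    = list(family = "binomial"),
  sprouting   = list(family = "binomial"),
  growth      = list(family = "poisson"),
  flowering   = list(family = "binomial"),
  flowercount = list(family = "poisson"),
  fruiting    = list(family = "binomial"),
  fruitcount  = list(family = "poisson")
)

#' Build the model design for one vital-rate response
#'
#' Produces one row per valid individual-year transition from a life
#' history table, with the response value and the covariate vector used by
#' the vital-rate models. Rows whose conditioning event fails are
#' excluded: sprouting rows require survival to year t+1, growth and
#' flowering rows require sprouting in year t+1, flower-count (and
#' fruiting-chain) rows require flowering in year t. Under the historical
#' design each row additionally requires a known year t-1 state, and
#' covariates `siz_tm1`, `flwyn_tm1` and `grw_t = siz_t - siz_tm1` are
#' included; under the age-stage design `age` (years since first record)
#' replaces them.
#'
#' Climate covariates are merged by year: for each variable `v` of the
#' climate series the columns `v_t`, `v_tp1` (response year t+1) and
#' `v_tm1` (year t-1) are available. A `density` column present in the
#' table is carried through.
#'
#' @param table A life history table (see [simulate_individuals()]).
#' @param climate A [climate_series()] covering the table's years (and
#'   years t-1/t+1 used by lagged covariates), or `NULL` for none.
#' @param design `"historical"`, `"agestage"` or `"simple"`.
#' @param response One of `r paste(names(resp_defs), collapse = ", ")`.
#' @return Data frame with columns `id`, `year`, `response` and covariates.
#' @export
build_design <- function(table, climate = NULL,
                         design = c("historical", "agestage", "simple"),
                         response = "survival") {
  design <- match.arg(design)
  if (!response %in% names(resp_defs))
    ss_stop("invalid_argument", sprintf("unknown response '%s'", response))
  tab <- as.data.frame(table)
  tab <- tab[order(tab$id, tab$year), , drop = FALSE]

  ## previous-year state (same individual, consecutive year)
  n <- nrow(tab)
  prev_ok <- c(FALSE, tab$id[-1] == tab$id[-n] & tab$year[-1] == tab$year[-n] + 1)
  siz_tm1 <- c(NA, tab$size[-n]); siz_tm1[!prev_ok] <- NA
  flw_tm1 <- c(NA, as.numeric(tab$flowering[-n])); flw_tm1[!prev_ok] <- NA

  first_year <- ave(tab$year, tab$id, FUN = min)
  age <- tab$year - first_year + 1

  cov <- data.frame(id = tab$id, year = tab$year,
                    siz_t = tab$size, flwyn_t = as.numeric(tab$flowering))
  if (design == "historical") {
    cov$siz_tm1 <- siz_tm1
    cov$flwyn_tm1 <- flw_tm1
    cov$grw_t <- cov$siz_t - cov$siz_tm1
  } else if (design == "agestage") {
    cov$age <- age
  }
  if (!is.null(tab$density)) cov$density <- tab$density

  if (!is.null(climate)) {
    yrs_used <- sort(unique(c(tab$year, tab$year + 1, tab$year - 1)))
    yrs_need <- sort(unique(c(tab$year, tab$year + 1)))
    if (!all(yrs_need %in% climate$year))
      ss_stop("missing_data", "climate series does not cover all table years")
    for (v in climate_vars(climate)) {
      look <- setNames(climate[[v]], climate$year)
      cov[[paste0(v, "_t")]] <- look[as.character(tab$year)]
      cov[[paste0(v, "_tp1")]] <- look[as.character(tab$year + 1)]
      cov[[paste0(v, "_tm1")]] <- look[as.character(tab$year - 1)]
    }
  }

  keep <- switch(response,
    survival = !is.na(tab$surv_next),
    sprouting = !is.na(tab$surv_next) & tab$surv_next == 1 & !is.na(tab$sprout_next),
    growth = !is.na(tab$sprout_next) & tab$sprout_next == 1 & !is.na(tab$size_next),
    flowering = !is.na(tab$sprout_next) & tab$sprout_next == 1 & !is.na(tab$flw_next),
    flowercount = tab$flowering == 1 & !is.na(tab$flowers),
    fruiting = tab$flowering == 1 & !is.na(tab$fruited),
    fruitcount = tab$flowering == 1 & !is.na(tab$fruited) & tab$fruited == 1 &
      !is.na(tab$fruits)
  )
  if (design == "historical") keep <- keep & !is.na(siz_tm1)

  resp <- switch(response,
    survival = as.numeric(tab$surv_next),
    sprouting = as.numeric(tab$sprout_next),
    growth = tab$size_next,
    flowering = as.numeric(tab$flw_next),
    flowercount = tab$flowers,
    fruiting = as.numeric(tab$fruited),
    fruitcount = tab$fruits
  )

  out <- cov[keep, , drop = FALSE]
  out$response <- resp[keep]
  ## target-size covariate for flowering (year t+1 size); flower-count
  ## models act on the current state so siz_target is the current size
  if (response == "flowering") out$siz_target <- tab$size_next[keep]
  if (response %in% c("flowercount", "fruiting", "fruitcount")) {
    out$siz_target <- out$siz_t
    if (!is.null(tab$flowers)) out$flw_t <- tab$flowers[keep]
  }
  rownames(out) <- NULL
  if (nrow(out) == 0) ss_stop("empty_design", sprintf("no rows for response '%s'", response))
  out
}

## ---------------------------------------------------------------------------
## fitting

term_matrix <- function(design, terms) {
  X <- matrix(1, nrow(design), 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) X <- cbind(X, term_value(tm, design))
  colnames(X) <- c("(Intercept)", terms)
  X
}

## zero-truncated Poisson regression by Newton scoring.
## score per observation: y - mu/(1 - exp(-mu)) (observed minus truncated
## mean); information weight: the truncated variance m (1 + mu - m) with
## m the truncated mean.
fit_truncpois <- function(X, y, offset = rep(0, length(y)), max_iter = 50) {
  beta <- c(log(max(mean(y), 1.01) - 1 + 0.5), rep(0, ncol(X) - 1))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(pmin(eta, 30))
    em <- exp(-mu)
    m <- mu / (1 - em)
    w <- pmax(m * (1 + mu - m), 1e-10)
    score <- drop(crossprod(X, y - m))
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(coef = beta, converged = FALSE, weights = w, info = info,
                  logLik = -Inf))
    ## damp large steps; clamp the intercept scale against separation
    step <- pmin(pmax(step, -5), 5)
    beta <- pmin(pmax(beta + step, -20), 20)
    if (max(abs(step)) < 1e-10) break
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(eta, 30))
  m <- mu / (1 - exp(-mu))
  w <- pmax(m * (1 + mu - m), 1e-10)
  list(coef = beta, converged = it < max_iter, weights = w,
       info = crossprod(X * w, X),
       logLik = sum(y * eta - mu - log(1 - exp(-mu)) - lgamma(y + 1)))
}

truncpois_year_offsets <- function(y, lp_fixed, year) {
  lev <- sort(unique(year))
  est <- se <- numeric(length(lev))
  X1 <- matrix(1, 1, 1)
  for (i in seq_along(lev)) {
    idx <- year == lev[i]
    f <- tryCatch(fit_truncpois(matrix(1, sum(idx), 1), y[idx],
                                offset = lp_fixed[idx]),
                  error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged)) { est[i] <- 0; se[i] <- 10; next }
    est[i] <- f$coef[1]
    se[i] <- sqrt(1 / max(f$info[1, 1], 1e-10))
    if (!is.finite(est[i]) || abs(est[i]) > 8) { est[i] <- sign(est[i]) * 8; se[i] <- 10 }
    if (!is.finite(se[i])) se[i] <- 10
  }
  list(levels = lev, est = est, se = se)
}

## per-year offset MLE with SE, one-parameter GLM given fixed linear predictor
year_offsets <- function(y, lp_fixed, year, family) {
  fam <- if (family == "binomial") binomial() else poisson()
  lev <- sort(unique(year))
  est <- se <- numeric(length(lev))
  for (i in seq_along(lev)) {
    idx <- year == lev[i]
    f <- tryCatch(
      glm(y[idx] ~ 1, offset = lp_fixed[idx], family = fam),
      error = function(e) NULL, warning = function(w) invokeRestart("muffleWarning"))
    f <- suppressWarnings(glm(y[idx] ~ 1, offset = lp_fixed[idx], family = fam))
    est[i] <- unname(coef(f)[1])
    se[i] <- sqrt(diag(vcov(f)))[1]
    if (!is.finite(est[i]) || abs(est[i]) > 8) { # separation within year
      est[i] <- sign(est[i]) * 8
      se[i] <- 10
    }
    if (!is.finite(se[i])) se[i] <- 10
  }
  list(levels = lev, est = est, se = se)
}

#' Fit one vital-rate model
#'
#' Maximum-likelihood binomial-logit or Poisson-log fit of a term list with
#' a year-level intercept. The default backend (`"ridge"`) fits shrunken
#' year offsets: raw per-year deviations are estimated against the fixed
#' linear predictor, the year variance is estimated by method of moments
#' (raw deviation variance minus mean squared standard error), deviations
#' are shrunk by `sigma2 / (sigma2 + se^2)`, and the fixed effects are
#' refit with the shrunken offsets. The `"glmm"` backend fits the same
#' model as a true mixed model with [lme4::glmer()].
#'
#' The parameter count used in AICc is the number of fixed coefficients
#' plus one (the year-variance term); `n` is the number of response rows.
#'
#' @param design Output of [build_design()] (or any data frame with
#'   `response`, `year` and covariate columns).
#' @param terms Character vector of terms (covariates and `"a:b"`
#'   interactions).
#' @param family `"binomial"` or `"poisson"`.
#' @param backend `"ridge"` (default) or `"glmm"`.
#' @param d_spr Stored intercept deviation for the resulting spec.
#' @param truncated Fit a zero-truncated Poisson likelihood (size
#'   responses are conditional on sprouting and therefore >= 1; a plain
#'   Poisson fit would be inconsistent for the generating coefficients).
#'   Ridge backend only.
#' @return A `vr_fit` object: list with `spec` ([vr_spec()]), `coef_se`,
#'   `logLik`, `k`, `n`, `AICc`, `converged`, `terms`, `family`.
#' @export
fit_vital_rate <- function(design, terms = character(),
                           family = c("binomial", "poisson"),
                           backend = c("ridge", "glmm"), d_spr = 0,
                           truncated = FALSE) {
  family <- match.arg(family)
  backend <- match.arg(backend)
  if (truncated && (family != "poisson" || backend != "ridge"))
    ss_stop("invalid_argument",
            "truncated fitting applies to Poisson responses with the ridge backend")
  terms <- as.character(terms)
  need <- terms_covariates(terms)
  miss <- setdiff(need, names(design))
  if (length(miss)) ss_stop("missing_covariate",
                            paste("design lacks covariates:", paste(miss, collapse = ", ")))
  use <- stats::complete.cases(design[, c("response", "year", need), drop = FALSE])
  design <- design[use, , drop = FALSE]
  if (nrow(design) < 1) ss_stop("empty_design", "no complete rows to fit")
  y <- design$response
  yr <- design$year
  fam <- if (family == "binomial") binomial() else poisson()

  if (backend == "glmm") {
    df <- design
    for (tm in terms) if (grepl(":", tm)) {
      nm <- gsub(":", "_x_", tm)
      df[[nm]] <- term_value(tm, design)
    }
    rhs <- if (length(terms)) paste(gsub(":", "_x_", terms), collapse = " + ") else "1"
    f <- stats::as.formula(paste("response ~", rhs, "+ (1 | year)"))
    fit <- tryCatch(lme4::glmer(f, data = df, family = fam),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(spec = NULL, converged = FALSE, terms = terms,
                            family = family, n = length(y)), class = "vr_fit"))
    }
    fe <- lme4::fixef(fit)
    names(fe) <- c("(Intercept)", terms)[seq_along(fe)]
    re <- lme4::ranef(fit)$year
    ye <- setNames(re[[1]], rownames(re))
    ysd <- sqrt(as.numeric(lme4::VarCorr(fit)$year[1]))
    k <- length(fe) + 1
    ll <- as.numeric(logLik(fit))
    conv <- length(fit@optinfo$conv$lme4) == 0
    spec <- vr_spec(family, terms, fe, year_effects = ye, year_sd = ysd, d_spr = d_spr)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    return(structure(list(spec = spec, coef_se = setNames(se, names(fe)),
                          logLik = ll, k = k, n = length(y),
                          AICc = aicc(ll, k, length(y)),
                          converged = conv, terms = terms, family = family,
                          backend = backend), class = "vr_fit"))
  }

  X <- term_matrix(design, terms)
  fit_fixed <- function(off) {
    if (truncated) fit_truncpois(X, y, offset = off)
    else suppressWarnings(glm.fit(X, y, family = fam, offset = off))
  }
  get_coef <- function(f) setNames(if (truncated) f$coef else coef(f), colnames(X))
  off <- rep(0, length(y))
  ylev <- sort(unique(yr))
  ysd <- 0
  ye <- setNames(rep(0, length(ylev)), ylev)
  f0 <- fit_fixed(off)
  if (length(ylev) >= 2) {
    for (it in 1:2) {
      lp <- drop(X %*% get_coef(f0))
      yo <- if (truncated) truncpois_year_offsets(y, lp, yr)
      else year_offsets(y, lp, yr, family)
      sigma2 <- max(0, var(yo$est) - mean(yo$se^2))
      shrunk <- yo$est * sigma2 / (sigma2 + yo$se^2)
      if (sigma2 == 0) shrunk <- rep(0, length(yo$est))
      ye <- setNames(shrunk, yo$levels)
      ysd <- sqrt(sigma2)
      off <- ye[as.character(yr)]
      f0 <- fit_fixed(off)
    }
  }
  cf <- get_coef(f0)
  conv <- isTRUE(f0$converged) && all(is.finite(cf)) && all(abs(cf) < 25)
  ll <- if (truncated) f0$logLik
  else family_loglik(y, drop(X %*% cf) + off, family)
  k <- ncol(X) + 1
  n <- length(y)
  ## Wald SEs from the weighted cross-product at the optimum
  XtWX <- if (truncated) f0$info else crossprod(X * sqrt(f0$weights))
  se <- tryCatch(sqrt(diag(solve(XtWX))), error = function(e) rep(NA_real_, ncol(X)))
  spec <- if (conv) vr_spec(family, terms, cf, year_effects = ye,
                            year_sd = ysd, d_spr = d_spr) else NULL
  structure(list(spec = spec, coef_se = setNames(se, colnames(X)),
                 logLik = ll, k = k, n = n, AICc = aicc(ll, k, n),
                 converged = conv, terms = terms, family = family,
                 backend = backend), class = "vr_fit")
}

family_loglik <- function(y, lp, family) {
  if (family == "binomial") {
    p <- plogis(lp)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mu <- exp(lp)
    sum(stats::dpois(y, mu, log = TRUE))
  }
}

#' @export
print.vr_fit <- function(x, ...) {
  cat("vital-rate fit (", x$family, ", backend ", x$backend %||% "?", ")\n", sep = "")
  if (!x$converged) cat("  ** non-converged **\n")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f\n", x$n, x$k,
              x$logLik %||% NA, x$AICc %||% NA))
  invisible(x)
}

## ---------------------------------------------------------------------------
## model enumeration & selection

#' Enumerate all reduced models of a global model
#'
#' All subsets of the global model's main effects and two-way interactions
#' respecting marginality: an interaction `"a:b"` appears only in models
#' containing both `a` and `b`.
#'
#' @param mains Character vector of main-effect covariates.
#' @param interactions Character vector of `"a:b"` interactions (default
#'   none).
#' @return List of term vectors (including the intercept-only model
#'   `character(0)`).
#' @export
enumerate_reduced_models <- function(mains, interactions = character()) {
  mains <- as.character(mains)
  interactions <- as.character(interactions)
  out <- list()
  nm <- length(mains)
  for (mask in 0:(2^nm - 1)) {
    mset <- mains[bitwAnd(mask, 2^(seq_len(nm) - 1)) > 0]
    ok_int <- interactions[vapply(interactions, function(i) {
      all(strsplit(i, ":", fixed = TRUE)[[1]] %in% mset)
    }, logical(1))]
    ni <- length(ok_int)
    for (imask in 0:(2^ni - 1)) {
      iset <- if (ni) ok_int[bitwAnd(imask, 2^(seq_len(ni) - 1)) > 0] else character()
      out[[length(out) + 1]] <- c(mset, iset)
    }
  }
  out
}

#' Select among candidate vital-rate fits by AICc
#'
#' Returns the lowest-AICc converged fit, unless a converged fit within
#' `delta` AICc units of the best has strictly fewer parameters, in which
#' case the fewest-parameter such fit wins. Ties are broken by lower AICc,
#' then by lexicographic term order. Non-converged fits are excluded.
#'
#' @param fits List of `vr_fit` objects.
#' @param delta Parsimony window (default 2.0).
#' @return The selected `vr_fit`.
#' @export
select_model <- function(fits, delta = 2.0) {
  ok <- Filter(function(f) isTRUE(f$converged) && is.finite(f$AICc), fits)
  if (length(ok) == 0) ss_stop("selection_error", "all candidate fits failed to converge")
  a <- vapply(ok, `[[`, numeric(1), "AICc")
  k <- vapply(ok, `[[`, numeric(1), "k")
  key <- vapply(ok, function(f) paste(sort(f$terms), collapse = "|"), character(1))
  best <- min(a)
  win <- which(a <= best + delta)
  kmin <- min(k[win])
  cand <- win[k[win] == kmin]
  cand <- cand[order(a[cand], key[cand])]
  ok[[cand[1]]]
}

#' Model-selection table
#'
#' @param fits List of `vr_fit` objects.
#' @return Data frame with terms, k, logLik, AICc and delta-AICc, sorted by
#'   AICc (non-converged fits flagged).
#' @export
model_selection_table <- function(fits) {
  df <- data.frame(
    terms = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)",
      character(1)),
    k = vapply(fits, function(f) f$k %||% NA_real_, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik %||% NA_real_, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc %||% NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1))
  )
  df <- df[order(df$AICc), , drop = FALSE]
  df$delta_AICc <- df$AICc - min(df$AICc, na.rm = TRUE)
  rownames(df) <- NULL
  df
}

## ---------------------------------------------------------------------------
## JSON serialization of specs

#' Serialize vital-rate specs to/from JSON
#'
#' @param spec A [vr_spec()] (or for `specs_to_json` a named list of them).
#' @param path File path.
#' @return `spec_from_json` returns a [vr_spec()]; `specs_from_json` a
#'   named list of them.
#' @export
spec_to_json <- function(spec, path) {
  x <- unclass(spec)
  ## named vectors must serialize as objects, not bare arrays
  x$coef <- as.list(x$coef)
  x$year_effects <- as.list(x$year_effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vr_spec(x$family, x$terms %||% character(),
          coef = unlist(x$coef),
          year_effects = if (length(x$year_effects)) unlist(x$year_effects) else numeric(),
          year_sd = x$year_sd %||% 0, d_spr = x$d_spr %||% 0)
}
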