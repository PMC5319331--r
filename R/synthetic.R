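#' Declare a ground-truth parameter set for simulation
#'
#' Bundles true vital-rate specs (with their year-effect standard
#' deviations), the study design, initial population settings and plot
#' geometry, so individual life histories can be generated with known
#' parameters and every downstream stage tested against truth.
#'
#' @param specs Named list of [vr_spec()] objects (`survival`,
#'   `sprouting`, `growth`, `flowering` required; `flowercount`,
#'   `fruiting`, `fruitcount` optional). Coefficients may reference
#'   climate covariates as `<var>_t`, `<var>_tp1`, `<var>_tm1` and local
#'   `density`.
#' @param design `"historical"`, `"agestage"` or `"simple"`.
#' @param n0 Initial number of individuals (>= 1).
#' @param n_years Number of monitored years.
#' @param max_size Maximum size class.
#' @param init_size_mean Poisson mean of initial sizes (truncated to
#'   `1..max_size`).
#' @param plot Plot extent in metres, `c(width, height)`.
#' @param recruits_per_year New emergent individuals added each year.
#' @return A `true_parameter_set` object.
#' @export
true_parameter_set <- function(specs, design = "simple", n0 = 100,
                               n_years = 20, max_size = 3,
                               init_size_mean = 1.5, plot = c(20, 20),
                               recruits_per_year = 0) {
  if (n0 < 1) ss_stop("invalid_argument", "n0 must be >= 1")
  need <- c("survival", "sprouting", "growth", "flowering")
  miss <- setdiff(need, names(specs))
  if (length(miss)) ss_stop("invalid_argument",
                            paste("missing true specs:", paste(miss, collapse = ", ")))
  if (any(vapply(specs, function(s) s$year_sd, numeric(1)) < 0))
    ss_stop("invalid_argument", "year_sd must be >= 0")
  structure(list(specs = specs, design = design, n0 = n0, n_years = n_years,
                 max_size = max_size, init_size_mean = init_size_mean,
                 plot = plot, recruits_per_year = recruits_per_year),
            class = "true_parameter_set")
}

## covariates any spec in the set needs
params_covariates <- function(params)
  unique(unlist(lapply(params$specs, function(s) terms_covariates(s$terms))))

#' Simulate individual life histories from known parameters
#'
#' Each individual's yearly fate is drawn in the conditional order
#' survival -> sprouting -> size (truncated Poisson on `1..max_size`) ->
#' flowering -> flower count (-> fruiting -> fruit count when fruiting
#' models are configured). Covariates feeding each draw are size and
#' flowering status in year t plus, under the historical design, size and
#' flowering in year t-1 (or, under the age-stage design, years since
#' first record), the relevant climate values, and local density when any
#' spec uses it. A per-year random intercept, drawn from each rate's
#' year-effect standard deviation, is shared by all individuals in that
#' year.
#'
#' The returned table has one row per individual-year while alive, with
#' next-year transition outcomes (`surv_next`, `sprout_next`,
#' `size_next`, `flw_next`) recorded where simulated.
#'
#' @param params A [true_parameter_set()].
#' @param climate A [climate_series()] covering years `0..n_years + 1`
#'   relative to the first monitored year (lagged covariates look one
#'   year each way), or `NULL` when no spec uses climate.
#' @param seed Integer seed.
#' @return A `life_history` data frame.
#' @export
simulate_individuals <- function(params, climate = NULL, seed = 1L) {
  needcov <- params_covariates(params)
  state_cov <- c("siz_t", "flwyn_t", "siz_tm1", "flwyn_tm1", "grw_t", "age",
                 "density", "siz_target", "flw_t")
  climcov <- setdiff(grep("_(t|tp1|tm1)$", needcov, value = TRUE), state_cov)
  use_density <- "density" %in% needcov
  years <- seq_len(params$n_years)
  if (length(climcov)) {
    if (is.null(climate)) ss_stop("missing_data", "specs use climate but no series supplied")
    base <- sub("_(t|tp1|tm1)$", "", climcov)
    if (!all(base %in% climate_vars(climate)))
      ss_stop("missing_data", "climate series lacks required variables")
    if (!all(c(min(years) - 1, years, max(years) + 1) %in% climate$year))
      ss_stop("missing_data", "climate series must cover all simulated years +/- 1")
  }
  clook <- function(v, yr) {
    if (is.null(climate)) return(rep(0, length(yr)))
    setNames(climate[[v]], climate$year)[as.character(yr)]
  }

  with_seed(sub_seed(seed, "individuals"), {
    sp <- params$specs
    rates <- names(sp)
    eps <- sapply(rates, function(r)
      rnorm(params$n_years, 0, sp[[r]]$year_sd))
    eps <- matrix(eps, nrow = params$n_years,
                  dimnames = list(NULL, rates))

    m <- params$max_size
    n <- params$n0
    id <- seq_len(n)
    x <- runif(n, 0, params$plot[1]); y <- runif(n, 0, params$plot[2])
    size <- rtpois(n, rep(params$init_size_mean, n), m)
    size_prev <- size    # steady-state assumption for the year before entry
    flw_prev <- rep(0, n)
    alive <- rep(TRUE, n)
    entry <- rep(1L, n)
    next_id <- n + 1L

    cov_now <- function(idx, t) {
      cov <- list(siz_t = size[idx], flwyn_t = flw[idx])
      if (params$design == "historical") {
        cov$siz_tm1 <- size_prev[idx]
        cov$flwyn_tm1 <- flw_prev[idx]
        cov$grw_t <- cov$siz_t - cov$siz_tm1
      } else if (params$design == "agestage") {
        cov$age <- t - entry[idx] + 1
      }
      for (cc in climcov) {
        v <- sub("_(t|tp1|tm1)$", "", cc)
        lag <- sub(".*_", "", cc)
        yr <- t + switch(lag, t = 0, tp1 = 1, tm1 = -1)
        cov[[cc]] <- rep(clook(v, yr), length(idx))
      }
      if (use_density) cov$density <- dens[idx]
      cov
    }

    ## initial flowering from the flowering model at initial size
    flw <- rep(0, n)
    ic <- list(siz_t = size, flwyn_t = 0, siz_tm1 = size_prev, flwyn_tm1 = 0,
               grw_t = size - size_prev, age = 1, density = 0,
               siz_target = size)
    for (cc in climcov) ic[[cc]] <- rep(clook(sub("_(t|tp1|tm1)$", "", cc), 1),
                                        n)
    flw <- rbinom(n, 1, eval_rate(sp$flowering, ic, eps[1, "flowering"]))

    rows <- vector("list", params$n_years)
    for (t in years) {
      ai <- which(alive)
      if (length(ai) == 0 && params$recruits_per_year == 0) break
      if (params$recruits_per_year > 0) {
        k <- params$recruits_per_year
        newi <- seq(next_id, length.out = k)
        next_id <- next_id + k
        id <- c(id, newi); alive <- c(alive, rep(TRUE, k))
        x <- c(x, runif(k, 0, params$plot[1])); y <- c(y, runif(k, 0, params$plot[2]))
        ns <- rtpois(k, rep(params$init_size_mean, k), m)
        size <- c(size, ns); size_prev <- c(size_prev, ns)
        flw <- c(flw, rep(0, k)); flw_prev <- c(flw_prev, rep(0, k))
        entry <- c(entry, rep(t, k))
        ai <- which(alive)
      }
      dens <- rep(0, length(id))
      if (use_density) {
        emi <- ai[size[ai] > 0]
        key <- paste(floor(x), floor(y))
        cnt <- table(key[emi])
        d <- as.numeric(cnt[key]); d[is.na(d)] <- 0
        dens <- d
      }
      cv <- cov_now(ai, t)

      ## same-year reproduction
      flowers <- rep(0, length(ai))
      fl <- which(flw[ai] == 1)
      if (length(fl) && !is.null(sp$flowercount)) {
        cvf <- lapply(cv, function(z) if (length(z) > 1) z[fl] else z)
        cvf$siz_target <- cv$siz_t[fl]
        mu <- eval_rate(sp$flowercount, cvf, eps[t, "flowercount"])
        flowers[fl] <- rpois(length(fl), mu)
      } else if (length(fl)) flowers[fl] <- 1
      fruited <- rep(NA, length(ai)); fruits <- rep(NA_real_, length(ai))
      if (!is.null(sp$fruiting) && length(fl)) {
        cvf <- lapply(cv, function(z) if (length(z) > 1) z[fl] else z)
        cvf$flw_t <- flowers[fl]; cvf$siz_target <- cv$siz_t[fl]
        fruited[fl] <- rbinom(length(fl), 1, eval_rate(sp$fruiting, cvf, eps[t, "fruiting"]))
        fr <- fl[fruited[fl] == 1]
        fruits[fl] <- 0
        if (length(fr) && !is.null(sp$fruitcount)) {
          cvr <- lapply(cv, function(z) if (length(z) > 1) z[match(fr, fl)] else z)
          cvr <- lapply(cv, function(z) if (length(z) > 1) z[fr] else z)
          cvr$flw_t <- flowers[match(fr, fl)]
          fruits[fr] <- rpois(length(fr),
                              eval_rate(sp$fruitcount, cvr, eps[t, "fruitcount"]))
        }
      }

      ## transition to year t+1
      ps <- eval_rate(sp$survival, cv, eps[t, "survival"])
      surv <- rbinom(length(ai), 1, ps)
      pp <- eval_rate(sp$sprouting, cv, eps[t, "sprouting"])
      spr <- ifelse(surv == 1, rbinom(length(ai), 1, pp), NA)
      mu_g <- eval_rate(sp$growth, cv, eps[t, "growth"])
      size_nxt <- rep(NA_real_, length(ai))
      gi <- which(!is.na(spr) & spr == 1)
      if (length(gi)) size_nxt[gi] <- rtpois(length(gi), mu_g[gi], m)
      size_nxt[!is.na(spr) & spr == 0] <- 0
      flw_nxt <- rep(NA_real_, length(ai))
      if (length(gi)) {
        cvg <- lapply(cv, function(z) if (length(z) > 1) z[gi] else z)
        cvg$siz_target <- size_nxt[gi]
        flw_nxt[gi] <- rbinom(length(gi), 1,
                              eval_rate(sp$flowering, cvg, eps[t, "flowering"]))
      }
      flw_nxt[!is.na(spr) & spr == 0] <- 0

      last_year <- t == params$n_years
      rows[[t]] <- data.frame(
        id = id[ai], year = t, alive = 1,
        sprouted = as.numeric(size[ai] > 0), size = size[ai],
        flowering = flw[ai], flowers = flowers,
        fruited = fruited, fruits = fruits,
        x = x[ai], y = y[ai],
        density = if (use_density) dens[ai] else NA_real_,
        surv_next = if (last_year) NA_real_ else as.numeric(surv),
        sprout_next = if (last_year) NA_real_ else as.numeric(spr),
        size_next = if (last_year) NA_real_ else size_nxt,
        flw_next = if (last_year) NA_real_ else flw_nxt)

      ## advance state
      size_prev[ai] <- size[ai]; flw_prev[ai] <- flw[ai]
      alive[ai] <- surv == 1
      size[ai] <- ifelse(surv == 1, ifelse(spr == 1, size_nxt, 0), NA)
      flw[ai] <- ifelse(surv == 1, ifelse(spr == 1, flw_nxt, 0), NA)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$id, out$year), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("life_history", "data.frame")
    attr(out, "design") <- params$design
    attr(out, "max_size") <- params$max_size
    out
  })
}

#' Validate life-history table invariants
#'
#' Checks: rows only while alive with no gaps after death, dormant rows
#' (alive, not sprouted) have size 0 and are non-flowering, sizes lie in
#' `0..max_size`, and flower/fruit counts are 0 (or absent) when not
#' flowering.
#'
#' @param table A life history table.
#' @param max_size Maximum size class (default from attribute).
#' @return `TRUE` invisibly; stops with a validation error otherwise.
#' @export
validate_life_history <- function(table, max_size = attr(table, "max_size") %||% Inf) {
  tab <- as.data.frame(table)
  bad <- tab$sprouted == 0 & (tab$size != 0 | tab$flowering != 0)
  if (any(bad)) ss_stop("validation_error", "dormant rows must have size 0 and no flowering")
  if (any(tab$size < 0 | tab$size > max_size))
    ss_stop("validation_error", "size out of range")
  if (any(tab$flowering == 0 & !is.na(tab$flowers) & tab$flowers > 0))
    ss_stop("validation_error", "flower counts must be 0 when not flowering")
  if (any(tab$flowering == 1 & tab$size < 1))
    ss_stop("validation_error", "flowering requires size >= 1")
  sp <- split(tab$year, tab$id)
  if (any(vapply(sp, function(y) any(diff(sort(y)) != 1), logical(1))))
    ss_stop("validation_error", "individual years must be consecutive while alive")
  invisible(TRUE)
}

#' Censor a true life-history table to the observer's view
#'
#' Produces what a field observer reconstructs: an individual is first
#' seen at its first emergence and rows exist from then until its last
#' emergence, with intervening non-emergent years reconstructed as
#' vegetative dormancy. Trailing years without emergence are unobserved:
#' if the trailing gap through `study_end` is at least `k` years the
#' individual is flagged ambiguous (dead-or-dormant) and, under the
#' default `presume_dead` rule, its survival response in the last
#' emergent year is set to 0; shorter trailing gaps leave that response
#' censored (`NA`). Individuals that never emerged are absent entirely.
#'
#' @param truth A true life history table from [simulate_individuals()].
#' @param study_end Last monitored year (default: last year in `truth`).
#' @param k Trailing-gap threshold in years (default 3).
#' @param presume_dead Treat gaps `>= k` as death in the year after last
#'   emergence (default `TRUE`).
#' @return A `life_history` table with an `ambiguous` column and attribute
#'   `ambiguous_ids`.
#' @export
censor_to_observed <- function(truth, study_end = NULL, k = 3,
                               presume_dead = TRUE) {
  tab <- as.data.frame(truth)
  study_end <- study_end %||% max(tab$year)
  out <- lapply(split(tab, tab$id), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    em <- d$year[d$sprouted == 1]
    if (length(em) == 0) return(NULL)
    span <- d$year >= min(em) & d$year <= max(em)
    o <- d[span, , drop = FALSE]
    o$ambiguous <- FALSE
    ## observer-reconstructed transition outcomes within the span
    nlast <- nrow(o)
    if (nlast > 1) {
      o$surv_next[-nlast] <- 1
      o$sprout_next[-nlast] <- o$sprouted[-1]
      o$size_next[-nlast] <- o$size[-1]
      o$flw_next[-nlast] <- o$flowering[-1]
    }
    gap <- study_end - max(em)
    if (gap >= k) {
      o$ambiguous <- TRUE
      o$surv_next[nlast] <- if (presume_dead) 0 else NA
      o$sprout_next[nlast] <- NA
      o$size_next[nlast] <- NA
      o$flw_next[nlast] <- NA
    } else if (gap > 0) {
      o$surv_next[nlast] <- NA
      o$sprout_next[nlast] <- NA
    }
    o
  })
  res <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(res) <- NULL
  class(res) <- c("life_history", "data.frame")
  attr(res, "design") <- attr(truth, "design")
  attr(res, "max_size") <- attr(truth, "max_size")
  attr(res, "ambiguous_ids") <- unique(res$id[res$ambiguous])
  res
}

#' Read/write life-history tables as CSV
#'
#' One row per individual-year.
#'
#' @param table A life history table.
#' @param path File path.
#' @return `read_life_history` returns a `life_history` data frame.
#' @export
write_life_history <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_history
#' @export
read_life_history <- function(path) {
  out <- read.csv(path)
  class(out) <- c("life_history", "data.frame")
  out
}
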