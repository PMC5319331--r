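#' Construct a climate series
#'
#' A climate series is a data frame with a `year` column and one numeric
#' column per climate variable (e.g. mean annual temperature, total annual
#' precipitation, winter frost days, spring sunshine hours), carrying a
#' provenance tag (`"observed"`, `"simulated"` or `"corrected"`).
#'
#' @param df Data frame with a `year` column and numeric variable columns.
#' @param provenance One of `"observed"`, `"simulated"`, `"corrected"`.
#' @return A `climate_series` data frame.
#' @export
climate_series <- function(df, provenance = "observed") {
  if (!"year" %in% names(df)) ss_stop("invalid_argument", "climate series needs a 'year' column")
  if (anyDuplicated(df$year)) ss_stop("invalid_argument", "duplicate years in climate series")
  df <- df[order(df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("climate_series", "data.frame"), provenance = provenance)
}

climate_vars <- function(series) setdiff(names(series), "year")

#' Generate a synthetic climate series
#'
#' Draws one value per variable per year. Values are independent normals
#' around a (possibly trending) mean; variables declared `type = "nonneg"`
#' (e.g. precipitation) are truncated at zero and `type = "count"` (e.g.
#' frost days) are additionally rounded. A deterministic `shape` function
#' of the year index can be supplied to build scenario series (ramps,
#' humps) for forecasting experiments.
#'
#' @param n_years Number of years (>= 1).
#' @param variable_specs Named list; each element a list with `mean`, `sd`
#'   and optionally `type` (`"normal"`, `"nonneg"`, `"count"`), `trend`
#'   (additive change per year) and `shape` (function of 1-based year index
#'   returning an additive deviation).
#' @param seed Integer seed; same seed gives an identical series.
#' @param start_year First calendar year.
#' @param provenance Provenance tag for the result.
#' @return A [climate_series()].
#' @export
gen_climate_series <- function(n_years, variable_specs, seed = 1L,
                               start_year = 1L, provenance = "simulated") {
  if (length(n_years) != 1 || is.na(n_years) || n_years < 1)
    ss_stop("invalid_argument", "n_years must be >= 1")
  out <- data.frame(year = seq(start_year, length.out = n_years))
  with_seed(sub_seed(seed, "climate"), {
    for (v in names(variable_specs)) {
      sp <- variable_specs[[v]]
      if (is.null(sp$mean)) ss_stop("invalid_argument", sprintf("variable '%s' needs a mean", v))
      sdv <- sp$sd %||% 0
      if (is.na(sdv) || sdv < 0) ss_stop("invalid_argument", sprintf("negative sd for '%s'", v))
      idx <- seq_len(n_years)
      mu <- sp$mean + (sp$trend %||% 0) * (idx - 1)
      if (!is.null(sp$shape)) mu <- mu + vapply(idx, sp$shape, numeric(1))
      x <- mu + rnorm(n_years, 0, sdv)
      type <- sp$type %||% "normal"
      if (type %in% c("nonneg", "count")) x <- pmax(x, 0)
      if (type == "count") x <- round(x)
      out[[v]] <- x
    }
  })
  climate_series(out, provenance = provenance)
}

#' Bias-correct a simulated climate series against observations
#'
#' Each variable of the simulated series is shifted so that its mean over
#' the overlapping years equals the observed mean over the same years
#' (difference-of-means correction). For variables listed in `ratio_vars`
#' (typically precipitation) a ratio-of-means correction is applied
#' instead.
#'
#' @param simulated,observed [climate_series()] objects with a non-empty
#'   overlap in years and shared variable columns.
#' @param ratio_vars Character vector of variables corrected by ratio of
#'   means rather than difference (default none).
#' @return The corrected simulated series (provenance `"corrected"`), with
#'   attribute `correction` holding the per-variable shift/factor.
#' @export
bias_correct <- function(simulated, observed, ratio_vars = character()) {
  ov <- intersect(simulated$year, observed$year)
  if (length(ov) == 0) ss_stop("alignment_error", "no overlapping years between series")
  vars <- intersect(climate_vars(simulated), climate_vars(observed))
  if (length(vars) == 0) ss_stop("alignment_error", "no shared climate variables")
  out <- as.data.frame(simulated)
  corr <- list()
  for (v in vars) {
    mo <- mean(observed[[v]][observed$year %in% ov])
    ms <- mean(simulated[[v]][simulated$year %in% ov])
    if (v %in% ratio_vars) {
      if (ms == 0) ss_stop("alignment_error", sprintf("zero simulated mean for ratio correction of '%s'", v))
      f <- mo / ms
      out[[v]] <- out[[v]] * f
      corr[[v]] <- c(factor = f)
    } else {
      d <- mo - ms
      out[[v]] <- out[[v]] + d
      corr[[v]] <- c(shift = d)
    }
  }
  res <- climate_series(out, provenance = "corrected")
  attr(res, "correction") <- corr
  res
}

#' Running-mean climate inputs
#'
#' For every year `Y` with a complete preceding window, returns the mean of
#' each climate variable over years `Y - window_preceding .. Y` inclusive
#' (26 values with the default window of 25 preceding years). Years lacking
#' a full window are omitted, not padded.
#'
#' @param series A [climate_series()] with consecutive years.
#' @param window_preceding Number of preceding years included (default 25).
#' @return A data frame of windowed means, one row per emitted year.
#' @export
running_mean_inputs <- function(series, window_preceding = 25) {
  yrs <- series$year
  if (any(diff(yrs) != 1))
    ss_stop("invalid_argument", "running-mean inputs need consecutive years")
  w <- window_preceding + 1L
  if (nrow(series) < w)
    ss_stop("invalid_argument", "series shorter than one full window")
  vars <- climate_vars(series)
  keep <- seq(w, nrow(series))
  out <- data.frame(year = yrs[keep])
  for (v in vars) {
    cs <- cumsum(series[[v]])
    out[[v]] <- (cs[keep] - c(0, cs)[keep - w + 1L]) / w
  }
  out
}

#' Fit a derived-predictor regression
#'
#' Some predictors used by the vital-rate models (winter frost days, spring
#' sunshine hours) are absent from simulated climate output. This fits an
#' ordinary least-squares regression of the target on variables shared by
#' observed and simulated series, so the derived predictor can be imputed
#' for simulated years. Predictions are clipped to the physical bounds of
#' the target.
#'
#' @param observed A [climate_series()] containing `target` and the
#'   predictor columns.
#' @param target Name of the derived predictor column.
#' @param predictors Character vector of shared predictor columns.
#' @param bounds Length-2 numeric physical bounds for predictions
#'   (default `c(0, Inf)`; frost days should use `c(0, 366)`).
#' @return An object of class `derived_predictor` with a `predict` method.
#' @export
fit_derived_predictor <- function(observed, target, predictors,
                                  bounds = c(0, Inf)) {
  dat <- as.data.frame(observed)[, c(target, predictors), drop = FALSE]
  dat <- na.omit(dat)
  if (nrow(dat) < 10) ss_stop("invalid_argument", "need >= 10 observed years to fit a derived predictor")
  f <- stats::as.formula(paste(target, "~", paste(predictors, collapse = " + ")))
  fit <- lm(f, data = dat)
  if (fit$rank < length(predictors) + 1)
    ss_stop("fit_error", "rank-deficient derived-predictor fit")
  structure(list(fit = fit, target = target, predictors = predictors,
                 bounds = bounds),
            class = "derived_predictor")
}

#' @rdname fit_derived_predictor
#' @param object A `derived_predictor`.
#' @param newdata A climate series or data frame with the predictor columns.
#' @param ... Unused.
#' @export
predict.derived_predictor <- function(object, newdata, ...) {
  p <- predict(object$fit, newdata = as.data.frame(newdata))
  n_clip <- sum(p < object$bounds[1] | p > object$bounds[2])
  if (n_clip > 0)
    ss_warn("clipped_prediction", sprintf("%d derived-predictor values clipped to bounds", n_clip))
  pmin(pmax(p, object$bounds[1]), object$bounds[2])
}

#' Sunshine hours from monthly shortwave radiation
#'
#' Converts monthly mean surface shortwave radiation to bright-sunshine
#' hours through the Suehrcke relation: the squared ratio of the monthly
#' clearness index to its clear-sky value approximates the relative bright
#' sunshine duration. Site constants (clear-sky radiation, mean day length
#' and day counts per month) are configuration, not code; the result is the
#' monotone map `hours = (rad / clear_sky)^2 * day_length * days`, summed
#' over the supplied months (April-May for the spring sunshine covariate).
#'
#' @param radiation Numeric vector of monthly mean shortwave radiation
#'   (W m^-2), one element per month.
#' @param constants List with numeric vectors `clear_sky` (same length and
#'   units as `radiation`), `day_length` (hours) and `days` (days per
#'   month).
#' @return Total sunshine hours over the supplied months.
#' @export
sunshine_from_radiation <- function(radiation, constants) {
  cs <- constants$clear_sky
  dl <- constants$day_length
  nd <- constants$days
  if (length(cs) != length(radiation) || length(dl) != length(radiation) ||
      length(nd) != length(radiation))
    ss_stop("invalid_argument", "constants must match the number of months")
  if (any(radiation < 0)) ss_stop("invalid_argument", "radiation must be >= 0")
  ratio <- radiation / cs
  if (any(ratio > 1)) {
    ss_warn("clipped_prediction", "radiation above clear-sky bound clipped")
    ratio <- pmin(ratio, 1)
  }
  sum(ratio^2 * dl * nd)
}

#' Read/write climate series CSV
#'
#' @param series A [climate_series()].
#' @param path File path.
#' @return `read_climate_csv` returns a [climate_series()].
#' @export
write_climate_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$provenance <- attr(series, "provenance") %||% "observed"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- read.csv(path)
  prov <- if ("provenance" %in% names(df)) df$provenance[1] else "observed"
  df$provenance <- NULL
  climate_series(df, provenance = prov)
}
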