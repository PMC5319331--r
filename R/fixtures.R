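#' Species-analogue synthetic fixtures
#'
#' Ready-made demographic model bundles with known generating parameters,
#' built to mirror the qualitative sign structures of the three study
#' systems on small state spaces. All three trajectory fixtures use the
#' stage-pair (historical) design, because the cross-year cost of growth
#' (the negative `grw_t` and consecutive-emergence `siz_t:siz_tm1`
#' survival effects) is what makes an intermediate sprouting probability
#' optimal; an additive-logit density modifier on a rate unlinked to the
#' trait adds no fitness curvature of its own (see the methods vignette).
#'
#' \describe{
#'   \item{`"cypripedium"`}{Survival rises with current size but falls
#'     with growth and consecutive emergence; winter frost days deepen
#'     the growth cost, so the projected decline in frost days favours
#'     higher sprouting (upward optimum). Density acts on sprouting
#'     (adult and juvenile).}
#'   \item{`"candidum"`}{As `"cypripedium"`, but annual precipitation
#'     relieves the growth cost; a mid-century precipitation excursion
#'     therefore drives the optimum away and back (returning optimum).}
#'   \item{`"ophrys"`}{Survival declines with size, growth and
#'     reproduction; spring sunshine and precipitation deepen the size
#'     and growth costs, so the projected sunnier, wetter climate
#'     favours lower sprouting (downward optimum).}
#'   \item{`"ophrys_age"`}{An age-by-stage bundle (3 age classes in the
#'     small fixture) with size-dependent mortality, used to exercise
#'     the age-structured builder in equilibrium and invasion tests.}
#' }
#'
#' The matching [true_parameter_set()] for data simulation is attached
#' as attribute `truth`, and the plateau density used for calibration as
#' attribute `plateau_target`.
#'
#' @param analogue Which fixture to build.
#' @param calibrate Calibrate the Ricker modifier to the default plateau
#'   (default `TRUE`).
#' @return A [sprout_model()].
#' @export
fixture_model <- function(analogue = c("cypripedium", "candidum", "ophrys",
                                       "ophrys_age"),
                          calibrate = TRUE) {
  analogue <- match.arg(analogue)
  plateau <- 2.0
  grow <- vr_spec("poisson", "siz_t",
                  c("(Intercept)" = 0.45, "siz_t" = 0.3), year_sd = 0.1)
  flower <- vr_spec("binomial", "siz_target",
                    c("(Intercept)" = -1.6, "siz_target" = 0.75), year_sd = 0.2)
  nflow <- vr_spec("poisson", "siz_t",
                   c("(Intercept)" = -0.4, "siz_t" = 0.35), year_sd = 0.1)
  juv <- list(s_seedling = 0.35, q_juv = 0.5, seedling_stasis = TRUE)

  if (analogue %in% c("cypripedium", "candidum")) {
    space <- historical_state_space(max_size = 3,
                                    entry_stages = c("D", "V1", "V2"),
                                    juvenile = "simple")
    clim_terms <- if (analogue == "cypripedium")
      c("frost_tp1" = -0.1, "grw_t:frost_tp1" = -0.4)
    else c("precip_tp1" = -0.1, "grw_t:precip_tp1" = 0.4)
    surv_coef <- c("(Intercept)" = 2.8, "siz_t" = 0.3, "grw_t" = -0.5,
                   "siz_t:siz_tm1" = -0.8, "flwyn_t" = -1.5, clim_terms)
    specs <- list(
      survival = vr_spec("binomial", setdiff(names(surv_coef), "(Intercept)"),
                         surv_coef, year_sd = 0.2),
      sprouting = vr_spec("binomial", "siz_t",
                          c("(Intercept)" = 0.3, "siz_t" = 0.3), year_sd = 0.25),
      growth = grow, flowering = flower, flowercount = nflow)
    fec <- fecundity_params(seeds_per_fruit = 1000, germination = 8e-3,
                            fruit_set = 0.45,
                            juvenile = c(juv, list(entry_weights = c(V1 = 0.7, V2 = 0.3))))
    clim <- c(frost_tp1 = 0, precip_tp1 = 0)
    dd <- "sprouting"; design <- "historical"
  } else if (analogue == "ophrys") {
    space <- historical_state_space(max_size = 3,
                                    entry_stages = c("D", "V1", "V2"),
                                    juvenile = "simple")
    surv_coef <- c("(Intercept)" = 2.9, "siz_t" = -0.1, "grw_t" = -0.45,
                   "siz_t:siz_tm1" = -0.8, "flwyn_t" = -1.2,
                   "sun_t" = -0.1, "siz_t:sun_t" = -0.3,
                   "sprppt_t" = -0.1, "grw_t:sprppt_t" = -0.15)
    specs <- list(
      survival = vr_spec("binomial", setdiff(names(surv_coef), "(Intercept)"),
                         surv_coef, year_sd = 0.2),
      sprouting = vr_spec("binomial", "siz_t",
                          c("(Intercept)" = 0.3, "siz_t" = 0.3), year_sd = 0.25),
      growth = vr_spec("poisson", c("siz_t", "sprppt_t"),
                       c("(Intercept)" = 0.45, "siz_t" = 0.3, "sprppt_t" = 0.1),
                       year_sd = 0.1),
      flowering = vr_spec("binomial", c("siz_target", "sun_t"),
                          c("(Intercept)" = -1.6, "siz_target" = 0.75,
                            "sun_t" = -0.15), year_sd = 0.2),
      flowercount = nflow)
    fec <- fecundity_params(seeds_per_fruit = 1000, germination = 1.2e-2,
                            fruit_set = 0.45,
                            juvenile = c(juv, list(entry_weights = c(V1 = 0.7, V2 = 0.3))))
    clim <- c(sun_t = 0, sprppt_t = 0)
    dd <- "sprouting"; design <- "historical"
  } else { # ophrys_age
    space <- agestage_state_space(n_ages = 3, max_size = 3, n_juv = 1,
                                  entry_stages = c("D", "V1", "F1"))
    surv_coef <- c("(Intercept)" = 2.8, "siz_t" = -0.9, "flwyn_t" = -0.4,
                   "sun_t" = -0.1, "siz_t:sun_t" = -0.25, "sprppt_t" = -0.15)
    specs <- list(
      survival = vr_spec("binomial", setdiff(names(surv_coef), "(Intercept)"),
                         surv_coef, year_sd = 0.2),
      sprouting = vr_spec("binomial", "siz_t",
                          c("(Intercept)" = 0.6, "siz_t" = -0.5), year_sd = 0.25),
      growth = vr_spec("poisson", c("siz_t", "sprppt_t"),
                       c("(Intercept)" = 0.3, "siz_t" = 0.25, "sprppt_t" = 0.1),
                       year_sd = 0.1),
      flowering = vr_spec("binomial", "sun_t",
                          c("(Intercept)" = -0.4, "sun_t" = -0.15), year_sd = 0.2),
      flowercount = vr_spec("poisson", character(), c("(Intercept)" = 0.2),
                            year_sd = 0.1))
    fec <- fecundity_params(seeds_per_fruit = 1500, germination = 5e-3,
                            fruit_set = 0.5,
                            juvenile = c(juv, list(s_seedling = 0.4,
                                                   entry_weights = c(V1 = 0.8, F1 = 0.2))))
    clim <- c(sun_t = 0, sprppt_t = 0)
    dd <- "sprouting"; design <- "agestage"
  }
  model <- sprout_model(space, specs, fec,
                        climate_spec = list(mean = clim,
                                            sd = setNames(rep(1, length(clim)),
                                                          names(clim))),
                        area = 100, dd_rate = dd)
  if (calibrate) model$ricker <- calibrate_ricker(model, plateau)
  attr(model, "plateau_target") <- plateau
  attr(model, "truth") <- true_parameter_set(
    specs, design = design, n0 = 200, n_years = 20, max_size = 3,
    init_size_mean = 1.5, plot = c(20, 20))
  model
}

#' Climate scenarios for the analogue fixtures
#'
#' Deterministic forecast series (plus optional noise) whose shapes give
#' the three analogues their qualitative regimes: for the
#' Cypripedium-analogue, winter frost days decline steadily (warming);
#' for the candidum-analogue, annual precipitation rises mid-century and
#' returns; for the Ophrys-analogue, spring sunshine and spring
#' precipitation rise steadily. Values are on the standardized covariate
#' scales of the fixture specs (0 = monitoring-period mean). The first
#' `window` years hold the baseline so the first forecast year has a
#' complete running-mean window.
#'
#' @param analogue Fixture name.
#' @param n_years Total years (default 86: 60 forecast years plus a full
#'   26-year leading window).
#' @param window Leading baseline years (default 26).
#' @param sd Noise standard deviation (default 0, a smooth scenario).
#' @param seed Seed for the noise.
#' @return A [climate_series()].
#' @export
fixture_climate_scenario <- function(analogue = c("cypripedium", "candidum",
                                                  "ophrys"),
                                     n_years = 86, window = 26, sd = 0,
                                     seed = 1L) {
  analogue <- match.arg(analogue)
  span <- n_years - window
  ramp <- function(to) function(i) to * pmax(0, i - window) / span
  ## the excursion completes one full running-mean window before the series
  ## ends, so the final windowed climate has returned to baseline
  hspan <- max(span - window, 2)
  hump <- function(amp) function(i)
    amp * pmax(0, sin(pi * pmin(pmax(0, i - window) / hspan, 1)))
  specs <- switch(analogue,
    cypripedium = list(frost = list(mean = 0, sd = sd, shape = ramp(-2)),
                       precip = list(mean = 0, sd = sd)),
    candidum = list(frost = list(mean = 0, sd = sd),
                    precip = list(mean = 0, sd = sd, shape = hump(1.5))),
    ophrys = list(sun = list(mean = 0, sd = sd, shape = ramp(1)),
                  sprppt = list(mean = 0, sd = sd, shape = ramp(1))))
  gen_climate_series(n_years, specs, seed = seed)
}
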