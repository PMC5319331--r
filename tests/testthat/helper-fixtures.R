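## cached calibrated fixture bundles (calibration is deterministic, so one
## copy per test file is enough)
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(analogue) {
  if (is.null(.fixture_cache[[analogue]]))
    .fixture_cache[[analogue]] <- fixture_model(analogue)
  .fixture_cache[[analogue]]
}

## intercept-only specs with every rate at a fixed probability/mean;
## logit/log intercepts chosen so rates are exactly the stated values
const_specs <- function(p_surv = 0.9, p_spr = 0.7, mu_size = 1.5,
                        p_flw = 0.3, mu_flowers = 1.2, year_sd = 0) {
  list(
    survival = vr_spec("binomial", coef = c("(Intercept)" = qlogis(p_surv)),
                       year_sd = year_sd),
    sprouting = vr_spec("binomial", coef = c("(Intercept)" = qlogis(p_spr)),
                        year_sd = year_sd),
    growth = vr_spec("poisson", coef = c("(Intercept)" = log(mu_size)),
                     year_sd = year_sd),
    flowering = vr_spec("binomial", coef = c("(Intercept)" = qlogis(p_flw)),
                        year_sd = year_sd),
    flowercount = vr_spec("poisson", coef = c("(Intercept)" = log(mu_flowers)),
                          year_sd = year_sd))
}

## smallest useful toy bundle: one seedling + dormant/V1/F1 adult stages
toy_model <- function(p_surv = 0.9, p_spr = 0.7, p_flw = 0.3,
                      recruits_expected = 1, dd_rate = NULL) {
  space <- simple_state_space(max_size = 1, entry_stages = c("D", "V1"))
  fec <- fecundity_params(seeds_per_fruit = 100,
                          germination = recruits_expected / (100 * 0.5 * 1.2),
                          fruit_set = 0.5,
                          juvenile = list(s_seedling = 0.4, q_juv = 0.5,
                                          entry_weights = c(V1 = 1)))
  sprout_model(space, const_specs(p_surv, p_spr, 1e-9, p_flw, 1.2), fec,
               climate_spec = list(mean = numeric(), sd = numeric()),
               area = 100, dd_rate = dd_rate)
}

## random small bundle on a random design, for property-style loops
random_model <- function(seed) {
  set.seed(seed)
  design <- sample(c("simple", "historical", "agestage"), 1)
  ms <- sample(2:3, 1)
  space <- switch(design,
    simple = simple_state_space(ms, c("D", "V1")),
    historical = historical_state_space(ms, c("D", "V1"), "simple"),
    agestage = agestage_state_space(n_ages = sample(2:3, 1), max_size = ms,
                                    n_juv = 1, entry_stages = c("D", "V1")))
  hist_terms <- if (design == "historical") c("siz_tm1", "grw_t") else character()
  age_terms <- if (design == "agestage") "age" else character()
  rnd_coef <- function(terms, int) {
    stats::setNames(c(int, stats::runif(length(terms), -0.5, 0.5)),
                    c("(Intercept)", terms))
  }
  st <- c("siz_t", "flwyn_t", hist_terms, age_terms)
  specs <- list(
    survival = vr_spec("binomial", st, rnd_coef(st, runif(1, 0.5, 2.5))),
    sprouting = vr_spec("binomial", "siz_t", rnd_coef("siz_t", runif(1, -1, 1))),
    growth = vr_spec("poisson", "siz_t", rnd_coef("siz_t", runif(1, -0.3, 0.6))),
    flowering = vr_spec("binomial", "siz_target",
                        rnd_coef("siz_target", runif(1, -2, 0))),
    flowercount = vr_spec("poisson", "siz_t", rnd_coef("siz_t", runif(1, -0.5, 0.5))))
  fec <- fecundity_params(seeds_per_fruit = sample(100:2000, 1),
                          germination = runif(1, 1e-4, 1e-2),
                          fruit_set = runif(1, 0.2, 0.8),
                          juvenile = list(s_seedling = runif(1, 0.2, 0.6),
                                          q_juv = runif(1, 0.3, 0.7),
                                          entry_weights = c(V1 = 1)))
  sprout_model(space, specs, fec,
               climate_spec = list(mean = numeric(), sd = numeric()),
               area = 100)
}

## intercept-only truth for simulation tests; extreme intercepts give
## degenerate (always/never) rates
const_truth <- function(surv_logit, spr_logit = qlogis(0.7), n0 = 50,
                        n_years = 6, year_sd = 0, design = "simple") {
  specs <- const_specs(year_sd = year_sd)
  specs$survival <- vr_spec("binomial", coef = c("(Intercept)" = surv_logit),
                            year_sd = year_sd)
  specs$sprouting <- vr_spec("binomial", coef = c("(Intercept)" = spr_logit),
                             year_sd = year_sd)
  specs$growth <- vr_spec("poisson", coef = c("(Intercept)" = log(1.5)),
                          year_sd = year_sd)
  true_parameter_set(specs, design = design, n0 = n0, n_years = n_years,
                     max_size = 3)
}

## purpose-built ground truth for the parameter-recovery suite: the
## full-size historical design (max size 9) so that Poisson size
## truncation is negligible and all generating coefficients are
## estimable by the plain GLM fits
recovery_truth <- function() {
  specs <- list(
    survival = vr_spec("binomial", c("siz_t", "grw_t", "flwyn_t", "frost_tp1"),
                       c("(Intercept)" = 1.8, siz_t = 0.1, grw_t = -0.15,
                         flwyn_t = -0.4, frost_tp1 = -0.3), year_sd = 0.2),
    sprouting = vr_spec("binomial", c("siz_t", "precip_tp1"),
                        c("(Intercept)" = 0.8, siz_t = 0.2, precip_tp1 = -0.2),
                        year_sd = 0.25),
    growth = vr_spec("poisson", "siz_t",
                     c("(Intercept)" = 0.5, siz_t = 0.1), year_sd = 0.1),
    flowering = vr_spec("binomial", "siz_target",
                        c("(Intercept)" = -1.5, siz_target = 0.4), year_sd = 0.2),
    flowercount = vr_spec("poisson", "siz_t",
                          c("(Intercept)" = 0.3, siz_t = 0.15), year_sd = 0.1))
  true_parameter_set(specs, design = "historical", n0 = 500, n_years = 20,
                     max_size = 9, init_size_mean = 2, recruits_per_year = 40)
}

recovery_climate <- function(seed) {
  gen_climate_series(24, list(frost = list(mean = 0, sd = 1),
                              precip = list(mean = 0, sd = 1)),
                     seed = seed, start_year = 0)
}
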