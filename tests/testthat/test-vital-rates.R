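test_that("eval_rate computes the link-inverse linear predictor", {
  s0 <- vr_spec("binomial", coef = c("(Intercept)" = 0))
  expect_equal(eval_rate(s0, list()), 0.5)

  ## fitted sprouting intercepts of the two focal systems, hand-evaluated
  cyp <- vr_spec("binomial", coef = c("(Intercept)" = -2.065))
  expect_equal(eval_rate(cyp, list()), plogis(-2.065))
  expect_equal(eval_rate(cyp, list()), 0.1126, tolerance = 1e-3)

  oph <- vr_spec("binomial", coef = c("(Intercept)" = 0.237), d_spr = 0.844)
  expect_equal(eval_rate(oph, list()), plogis(1.081))
  expect_equal(round(eval_rate(oph, list()), 4), 0.7467)
  ## override beats the stored deviation
  expect_equal(eval_rate(oph, list(), d_spr = 0), plogis(0.237))

  ## terms, interactions, year deviation and offset combine additively
  sp <- vr_spec("binomial", c("a", "b", "a:b"),
                c("(Intercept)" = 0.5, a = 1, b = -0.5, "a:b" = 0.25))
  expect_equal(eval_rate(sp, list(a = 2, b = 3), year_dev = 0.1, offset = -0.2),
               plogis(0.5 + 2 - 1.5 + 1.5 + 0.1 - 0.2))
  expect_error(eval_rate(sp, list(a = 1)), class = "sproutess_missing_covariate")

  ## monotone in a covariate with positive coefficient and no interaction
  mono <- vr_spec("poisson", "x", c("(Intercept)" = 0.2, x = 0.7))
  xs <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(eval_rate(mono, list(x = xs))) > 0))
})

test_that("vr_spec validates its contract and serializes to JSON", {
  expect_error(vr_spec("binomial", "a", c("(Intercept)" = 0)),
               class = "sproutess_invalid_argument")
  sp <- vr_spec("poisson", "siz_t", c("(Intercept)" = 0.3, siz_t = 0.1),
                year_effects = c("1994" = 0.05, "1995" = -0.02),
                year_sd = 0.12, d_spr = 0.4)
  f <- tempfile(fileext = ".json")
  spec_to_json(sp, f)
  back <- spec_from_json(f)
  expect_equal(back$coef, sp$coef)
  expect_equal(back$year_effects, sp$year_effects)
  expect_equal(back$year_sd, sp$year_sd)
  expect_equal(back$d_spr, sp$d_spr)
})

test_that("design building counts rows and applies conditioning", {
  base <- function(id, yrs, sizes, spr = NULL) {
    n <- length(yrs)
    spr <- spr %||% as.numeric(sizes > 0)
    data.frame(id = id, year = yrs, alive = 1, sprouted = spr, size = sizes,
               flowering = 0, flowers = 0, fruited = NA, fruits = NA,
               x = 0.5, y = 0.5,
               surv_next = c(rep(1, n - 1), NA),
               sprout_next = c(spr[-1], NA),
               size_next = c(sizes[-1], NA),
               flw_next = c(rep(0, n - 1), NA))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  ## one individual, 3 consecutive years: exactly 1 historical survival row
  t3 <- base(1, 1:3, c(1, 2, 1))
  expect_equal(nrow(build_design(t3, NULL, "historical", "survival")), 1)
  ## simple design keeps both transition rows
  expect_equal(nrow(build_design(t3, NULL, "simple", "survival")), 2)

  ## sprouting rows only where survival to t+1 is known true
  t3$surv_next[2] <- 0
  d <- build_design(t3, NULL, "simple", "sprouting")
  expect_equal(nrow(d), 1)
  expect_equal(d$year, 1)

  ## ten individuals, 4 years, one dies after year 2: survival design has
  ## (individual-years with known history) - (post-death years) rows
  tabs <- lapply(1:10, function(i) base(i, 1:4, c(1, 1, 2, 1)))
  tabs[[4]] <- base(4, 1:2, c(1, 1))
  tabs[[4]]$surv_next[2] <- 0
  tab <- do.call(rbind, tabs)
  d <- build_design(tab, NULL, "historical", "survival")
  ## by hand: 9 survivors contribute years 2,3 (year 1 lacks history,
  ## year 4 lacks outcome) = 18; the casualty contributes year 2 only
  expect_equal(nrow(d), 19)
  expect_equal(sum(d$response == 0), 1)

  ## age design exposes years since first record
  da <- build_design(tab, NULL, "agestage", "survival")
  expect_equal(sort(unique(da$age)), 1:3)

  expect_error(build_design(tab, NULL, "simple", "nosuch"),
               class = "sproutess_invalid_argument")
  empty <- base(1, 1:2, c(1, 1)); empty$surv_next <- NA
  expect_error(build_design(empty, NULL, "simple", "survival"),
               class = "sproutess_empty_design")
})

test_that("intercept-only fits match closed-form Bernoulli MLEs", {
  d5050 <- data.frame(response = rep(0:1, each = 50), year = 1)
  f <- fit_vital_rate(d5050, family = "binomial")
  expect_equal(unname(f$spec$coef[["(Intercept)"]]), 0, tolerance = 1e-6)

  d8020 <- data.frame(response = rep(c(1, 0), c(80, 20)), year = 1)
  f2 <- fit_vital_rate(d8020, family = "binomial")
  expect_equal(unname(f2$spec$coef[["(Intercept)"]]), qlogis(0.8),
               tolerance = 1e-6)
  ## AICc identity holds on the returned fit
  expect_equal(f2$AICc, aicc(f2$logLik, f2$k, f2$n))
})

test_that("slope recovery: simulated logistic slope is within 3 SE", {
  set.seed(31)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x))
  d <- data.frame(response = y, siz_t = x, year = rep(1:20, length.out = n))
  f <- fit_vital_rate(d, "siz_t", family = "binomial")
  expect_true(f$converged)
  expect_lt(abs(f$spec$coef[["siz_t"]] - 0.5), 3 * f$coef_se[["siz_t"]])
})

test_that("ridge year offsets approximate the GLMM backend", {
  set.seed(77)
  ny <- 15; nper <- 120
  yr_eff <- rnorm(ny, 0, 0.5)
  d <- data.frame(year = rep(seq_len(ny), each = nper),
                  siz_t = rnorm(ny * nper))
  d$response <- rbinom(nrow(d), 1, plogis(0.3 + 0.4 * d$siz_t + yr_eff[d$year]))
  fr <- fit_vital_rate(d, "siz_t", family = "binomial", backend = "ridge")
  fg <- fit_vital_rate(d, "siz_t", family = "binomial", backend = "glmm")
  expect_true(fr$converged && fg$converged)
  expect_lt(abs(fr$spec$coef[["siz_t"]] - fg$spec$coef[["siz_t"]]), 0.05)
  expect_lt(abs(fr$spec$coef[["(Intercept)"]] - fg$spec$coef[["(Intercept)"]]), 0.1)
  expect_lt(abs(fr$spec$year_sd - fg$spec$year_sd), 0.2)
  ## shrunken year offsets track the generating deviations
  expect_gt(cor(fr$spec$year_effects, yr_eff), 0.7)
})

test_that("reduced-model enumeration respects marginality", {
  m2 <- enumerate_reduced_models(c("A", "B"), "A:B")
  expect_length(m2, 5)
  keys <- sort(vapply(m2, function(t) paste(sort(t), collapse = ","), ""))
  expect_equal(keys, sort(c("", "A", "B", "A,B", "A,A:B,B")))
  expect_length(enumerate_reduced_models("A"), 2)

  big <- enumerate_reduced_models(c("A", "B", "C"), c("A:B", "B:C"))
  for (tm in big) {
    for (i in grep(":", tm, value = TRUE)) {
      expect_true(all(strsplit(i, ":")[[1]] %in% tm))
    }
  }
})

test_that("AICc-based selection prefers parsimony within the 2-unit window", {
  mk_fit <- function(aicc, k, terms) structure(
    list(AICc = aicc, k = k, terms = terms, converged = TRUE),
    class = "vr_fit")
  f5 <- mk_fit(100.0, 5, c("a", "b", "c", "d"))
  f3 <- mk_fit(101.5, 3, c("a", "b"))
  expect_identical(select_model(list(f5, f3)), f3)
  f3b <- mk_fit(102.5, 3, c("a", "b"))
  expect_identical(select_model(list(f5, f3b)), f5)
  expect_identical(select_model(list(f5)), f5)
  ## never returns a model above best + 2
  picked <- select_model(list(f5, f3, mk_fit(99.9, 6, letters[1:5])))
  expect_lte(picked$AICc, 99.9 + 2)
  ## ties broken by AICc then lexicographic terms
  g1 <- mk_fit(100.0, 2, "b"); g2 <- mk_fit(100.0, 2, "a")
  expect_identical(select_model(list(g1, g2)), g2)
  bad <- structure(list(converged = FALSE, terms = "a"), class = "vr_fit")
  expect_error(select_model(list(bad)), class = "sproutess_selection_error")
})

test_that("exhaustive selection recovers generating terms from simulated data", {
  hits <- 0
  for (rep in 1:5) {
    set.seed(500 + rep)
    n <- 6000
    d <- data.frame(siz_t = rpois(n, 2), frost = rnorm(n),
                    year = rep(1:20, length.out = n))
    d$response <- rbinom(n, 1, plogis(0.2 + 0.45 * d$siz_t - 0.4 * d$frost))
    cand <- enumerate_reduced_models(c("siz_t", "frost"), "siz_t:frost")
    fits <- lapply(cand, function(tm) fit_vital_rate(d, tm, family = "binomial"))
    sel <- select_model(fits)
    if (setequal(sel$terms, c("siz_t", "frost"))) hits <- hits + 1
  }
  expect_gte(hits, 4)
  ## the selection table is sorted with deltas from the best model
  tab <- model_selection_table(list(
    structure(list(AICc = 10, k = 2, terms = "a", logLik = -3, converged = TRUE),
              class = "vr_fit"),
    structure(list(AICc = 12, k = 3, terms = c("a", "b"), logLik = -2.5,
                   converged = TRUE), class = "vr_fit")))
  expect_equal(tab$delta_AICc, c(0, 2))
})
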