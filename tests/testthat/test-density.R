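test_that("local density counts emergent individuals per 1 m cell", {
  tab <- data.frame(
    id = 1:5, year = 1,
    sprouted = c(1, 1, 1, 1, 0), size = c(2, 1, 3, 1, 0), flowering = 0,
    flowers = 0, x = c(0.2, 0.8, 0.5, 3.4, 0.5), y = c(0.1, 0.9, 0.5, 3.9, 0.4),
    surv_next = NA, sprout_next = NA, size_next = NA, flw_next = NA,
    fruited = NA, fruits = NA, alive = 1)
  d <- local_density(tab)
  ## hand tally: three emergent plants share cell (0,0); one alone; the
  ## dormant plant inherits its cell's emergent count
  expect_equal(d$density, c(3, 3, 3, 1, 3))

  ## half-open cell assignment: a plant exactly on x = 1 is in the next cell
  tb <- tab[1:2, ]; tb$x <- c(0.999, 1.0); tb$y <- 0.5
  expect_equal(local_density(tb)$density, c(1, 1))

  expect_error(local_density(within(tab, x <- NA)),
               class = "sproutess_missing_data")
})

test_that("density screening classifies known generating slopes", {
  sim_dd <- function(slope, seed) {
    specs <- const_specs(p_surv = 0.85, p_spr = 0.7)
    specs$survival <- vr_spec("binomial", "density",
                              c("(Intercept)" = qlogis(0.85), density = slope))
    p <- true_parameter_set(specs, n0 = 900, n_years = 6, plot = c(12, 12))
    simulate_individuals(p, seed = seed)
  }
  neg <- screen_density(sim_dd(-0.3, 1), rates = list(survival = character()))
  expect_equal(neg$classification[neg$rate == "survival"], "negative")
  pos <- screen_density(sim_dd(0.3, 2), rates = list(survival = character()))
  expect_equal(pos$classification[pos$rate == "survival"], "positive")
  ## type-I error: a zero slope reads "none" in >= 90% of replicates
  nones <- sum(vapply(1:30, function(i) {
    s <- screen_density(sim_dd(0, 10 + i), rates = list(survival = character()))
    s$classification[s$rate == "survival"] == "none"
  }, logical(1)))
  expect_gte(nones, 27)
})

test_that("the Ricker modifier acts additively on the link scale", {
  p <- ricker_params(1, 0.01, "sprouting")
  expect_equal(apply_density_modifier(0.3, 50, p), 0.3 + 1 - 0.5)
  expect_equal(apply_density_modifier(0.3, 0, ricker_params(0, 0)), 0.3)
  ## probability strictly decreasing in N for beta > 0
  Ns <- seq(0, 100, by = 10)
  pr <- plogis(apply_density_modifier(qlogis(0.6), Ns, p))
  expect_true(all(diff(pr) < 0))
  expect_error(ricker_params(1, -0.1), class = "sproutess_invalid_argument")
})

test_that("the scalar Ricker map equilibrates at alpha / beta", {
  p <- ricker_params(1, 0.01)
  N <- 1
  for (i in 1:500) N <- N * exp(apply_density_modifier(0, N, p))
  expect_equal(N, 100, tolerance = 1e-10)
  ## doubling the target density doubles the equilibrium
  p2 <- ricker_params(1, 0.005)
  N <- 1
  for (i in 1:500) N <- N * exp(apply_density_modifier(0, N, p2))
  expect_equal(N, 200, tolerance = 1e-8)
})

test_that("Ricker calibration reaches the plateau and fails without growth", {
  m <- fixture_model("cypripedium", calibrate = FALSE)
  rp <- calibrate_ricker(m, 2.0)
  expect_lt(abs(attr(rp, "plateau") - 2.0), 0.02 * 2.0)
  ## stationarity: lambda = 1 at the calibrated plateau
  m$ricker <- rp
  lam <- dominant_lambda(build_annual_matrix(m, density = attr(rp, "plateau")))
  expect_lt(abs(lam - 1), 1e-3)
  ## doubling the target doubles the achieved plateau
  rp2 <- calibrate_ricker(m, 4.0)
  expect_lt(abs(attr(rp2, "plateau") - 4.0), 0.02 * 4.0)
  ## no asymptotic growth: lambda0 <= 1 at zero density
  dead <- m; dead$fec$germination <- 1e-6
  expect_error(calibrate_ricker(dead, 2.0),
               class = "sproutess_calibration_failure")
})

test_that("density-coupled iteration stays bounded under crowding", {
  for (i in 1:20) {
    m <- random_model(7000 + i)
    m$dd_rate <- "sprouting"
    lam0 <- dominant_lambda(build_annual_matrix(m))
    if (lam0 <= 1.002) next
    rp <- tryCatch(calibrate_ricker(m, 2.0), error = function(e) NULL)
    if (is.null(rp)) next
    m$ricker <- rp
    it <- sproutess:::iterate_density(m)
    expect_true(all(it$trajectory[-(1:100)] <= 20))
  }
})

test_that("the density-dependent rate is selected by priority with fallback", {
  m <- cached_fixture("cypripedium")
  screen <- data.frame(rate = c("survival", "sprouting", "flowering"),
                       slope = c(0.2, -0.4, -0.1), se = 0.05,
                       classification = c("positive", "negative", "negative"))
  sel <- select_dd_rate(screen, m, 2.0)
  expect_equal(as.character(sel), "sprouting")
  expect_s3_class(attr(sel, "ricker"), "ricker_params")

  ## first candidate (flowering: no modifier hook) fails, second succeeds
  screen2 <- data.frame(rate = c("flowering", "sprouting"),
                        slope = c(-0.3, -0.4), se = 0.05,
                        classification = "negative")
  sel2 <- select_dd_rate(screen2, m, 2.0,
                         priority = c("flowering", "sprouting"))
  expect_equal(as.character(sel2), "sprouting")

  none <- data.frame(rate = "survival", slope = 0.1, se = 0.05,
                     classification = "positive")
  expect_error(select_dd_rate(none, m, 2.0),
               class = "sproutess_selection_failure")
})

test_that("screened sprouting density dependence on fixture-like data selects sprouting", {
  m <- cached_fixture("cypripedium")
  truth <- attr(m, "truth")
  ## graft the negative conspecific-density response onto the generating
  ## sprouting model, as in the focal system
  truth$specs$sprouting <- vr_spec(
    "binomial", c("siz_t", "density"),
    c("(Intercept)" = 0.8, siz_t = 0.3, density = -0.35), year_sd = 0.25)
  truth$n0 <- 700; truth$n_years <- 8; truth$plot <- c(15, 15)
  cl <- gen_climate_series(12, list(frost = list(mean = 0, sd = 1),
                                    precip = list(mean = 0, sd = 1)),
                           seed = 4, start_year = 0)
  tab <- simulate_individuals(truth, cl, seed = 9)
  screen <- screen_density(tab, cl, design = "historical",
                           rates = list(survival = "siz_t",
                                        sprouting = "siz_t",
                                        flowering = "siz_t"))
  expect_equal(screen$classification[screen$rate == "sprouting"], "negative")
  sel <- select_dd_rate(screen, m, 2.0)
  expect_equal(as.character(sel), "sprouting")
})
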