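test_that("growth distribution is a renormalized truncated Poisson", {
  sp <- vr_spec("poisson", coef = c("(Intercept)" = log(2)))
  g <- growth_distribution(sp, data.frame(x = 1), max_size = 9)
  ref <- dpois(1:9, 2) / sum(dpois(1:9, 2))
  expect_equal(as.numeric(g), ref, tolerance = 1e-12)
  expect_equal(sum(g), 1, tolerance = 1e-12)

  ## vanishing mean concentrates on size 1
  tiny <- vr_spec("poisson", coef = c("(Intercept)" = -600))
  g0 <- growth_distribution(tiny, data.frame(x = 1), max_size = 5)
  expect_equal(as.numeric(g0), c(1, 0, 0, 0, 0))

  expect_error(growth_distribution(sp, data.frame(x = 1), 0),
               class = "sproutess_invalid_argument")
  expect_error(growth_distribution(vr_spec("binomial", coef = c("(Intercept)" = 0)),
                                   data.frame(x = 1), 3),
               class = "sproutess_invalid_argument")
})

test_that("transition entries follow the survival-sprouting kernel", {
  expect_equal(transition_entries(0.9, 0.8, 1, 0)$aD, 0.18)
  te <- transition_entries(0.9, 0.8, 0.5, 0.25)
  expect_equal(te$aV, 0.27)
  expect_equal(te$aF, 0.09)
  ## algebraic identity: aD + sum(aV + aF) = S when sum(g) = 1
  g <- c(0.2, 0.5, 0.3); Fk <- c(0.1, 0.4, 0.9)
  te <- transition_entries(0.87, 0.64, g, Fk)
  expect_equal(te$aD + sum(te$aV + te$aF), 0.87, tolerance = 1e-15)
})

test_that("a constant-rate toy model matches its hand-computed kernel", {
  S <- 0.9; P <- 0.7; Fl <- 0.3
  m <- toy_model(S, P, Fl, recruits_expected = 1.2)
  A <- build_annual_matrix(m)
  ## states: 1 seedling, 2 D, 3 V1, 4 F1; max size 1 so g = 1 at size 1
  expect_equal(dim(A), c(4, 4))
  expected <- matrix(0, 4, 4)
  expected[2, 2:4] <- S * (1 - P)
  expected[3, 2:4] <- S * P * (1 - Fl)
  expected[4, 2:4] <- S * P * Fl
  ## seedling: survival 0.4, sprouting 0.5 into V1 (D branch = stasis off)
  expected[2, 1] <- 0.4 * 0.5
  expected[3, 1] <- 0.4 * 0.5
  ## fecundity from the flowering column
  expected[1, 4] <- 1.2
  expect_equal(unclass(A), expected, ignore_attr = TRUE, tolerance = 1e-12)

  ## deterministic mode is reproducible
  expect_equal(unclass(build_annual_matrix(m)), unclass(A), ignore_attr = TRUE)
})

test_that("full-design matrices have the printed orders", {
  specs <- const_specs()
  specs$survival <- vr_spec("binomial", c("siz_t", "grw_t"),
                            c("(Intercept)" = 2, siz_t = 0.1, grw_t = -0.2))
  mc <- sprout_model(cypripedium_state_space(), specs, fecundity_params())
  Ac <- build_annual_matrix(mc)
  expect_equal(dim(Ac), c(395, 395))
  specs$survival <- vr_spec("binomial", c("siz_t", "age"),
                            c("(Intercept)" = 2, siz_t = 0.1, age = -0.05))
  mo <- sprout_model(ophrys_state_space(), specs, fecundity_params())
  expect_equal(dim(build_annual_matrix(mo)), c(173, 173))
})

test_that("survival conservation holds and structural zeros are respected", {
  for (i in 1:25) {
    m <- random_model(3000 + i)
    A <- build_annual_matrix(m)
    sc <- sproutess:::state_covariates(m$space)
    S <- eval_rate(m$specs$survival, sc$cov)
    colsum_tr <- colSums(A)[sc$idx] - A[m$space$fec_to, sc$idx]
    expect_lt(max(abs(colsum_tr - S)), 1e-12)
    ## no mass outside the admissible arcs
    arcs <- admissible_arcs(m$space)
    ok <- matrix(FALSE, m$space$n, m$space$n)
    ok[cbind(arcs$to, arcs$from)] <- TRUE
    ## seedling stasis rewires the (1 - q) juvenile branch onto itself
    juv <- which(is.na(m$space$states$cur_stage))
    ok[cbind(juv, juv)] <- TRUE
    expect_true(all(A[!ok] == 0))
  }
})

test_that("stochastic matrices average to the deterministic matrix", {
  m <- toy_model(0.85, 0.6, 0.35, recruits_expected = 1)
  m$specs <- const_specs(0.85, 0.6, 1e-9, 0.35, 1.2, year_sd = 0.05)
  Adet <- build_annual_matrix(m)
  n <- 4000
  acc <- matrix(0, 4, 4); acc2 <- matrix(0, 4, 4)
  for (i in seq_len(n)) {
    As <- build_annual_matrix(m, mode = "stochastic", seed = 40000 + i)
    acc <- acc + As; acc2 <- acc2 + As^2
  }
  mean_A <- acc / n
  se_A <- sqrt(pmax(acc2 / n - mean_A^2, 0) / n)
  ## small year variance: the Monte-Carlo mean approaches the deterministic
  ## entries up to the second-order Jensen gap; 3 MC SEs plus that bias bound
  nz <- unclass(Adet) > 0
  bias_bound <- 0.5 * 0.05^2 * unclass(Adet) + 3e-4
  expect_true(all(abs(mean_A - unclass(Adet))[nz] <=
                    (3 * se_A + bias_bound)[nz]))
})

test_that("stochastic mode resamples fitted years when a year table exists", {
  m <- toy_model(0.8, 0.6, 0.3)
  m$year_table <- data.frame(year = 1:3, survival = c(0.5, -0.5, 0),
                             sprouting = 0, growth = 0, flowering = 0,
                             flowercount = 0)
  draws <- replicate(50, {
    A <- build_annual_matrix(m, mode = "stochastic",
                             seed = sample.int(1e6, 1))
    attr(A, "context")$year_dev[["survival"]]
  })
  expect_true(all(draws %in% c(0.5, -0.5, 0)))
  expect_gt(length(unique(draws)), 1)
})

test_that("dominant eigenvalue matches closed forms and power iteration", {
  expect_equal(dominant_lambda(diag(5)), 1)
  A <- matrix(c(0, 0.5, 2, 0), 2, 2)   # lambda^2 = 1
  expect_equal(dominant_lambda(A), 1, tolerance = 1e-12)
  set.seed(99)
  R <- matrix(runif(2500), 50, 50)
  pl <- power_lambda(R)
  expect_lt(abs(dominant_lambda(R) - pl$lambda), 1e-6)
  expect_error(dominant_lambda(matrix(c(1, NA, 0, 1), 2)),
               class = "sproutess_numeric_error")
})

test_that("fecundity perturbation scales, documents asymmetry, and clips", {
  p <- fecundity_params(germination = 0.5)
  up <- perturb_fecundity(p, 0.1, "germination")
  expect_equal(up$germination, 0.55)
  back <- perturb_fecundity(perturb_fecundity(p, -0.1, "germination"),
                            0.1, "germination")
  expect_equal(back$germination, 0.5 * 0.99)
  expect_warning(cl <- perturb_fecundity(fecundity_params(germination = 0.95),
                                         0.1, "germination"),
                 class = "sproutess_clipped_fraction")
  expect_equal(cl$germination, 1)
})

test_that("projection matrices round-trip through MatrixMarket", {
  m <- toy_model()
  A <- build_annual_matrix(m)
  f <- tempfile(fileext = ".mtx")
  write_matrix_mtx(A, m$space, f)
  back <- read_matrix_mtx(f)
  expect_equal(back, unclass(A), ignore_attr = TRUE, tolerance = 1e-12)
  idx <- read_state_index(sub("\\.mtx$", ".index.csv", f))
  expect_equal(nrow(idx), m$space$n)
})
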