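test_that("resident equilibrium is a stationary attractor", {
  m <- cached_fixture("cypripedium")
  res <- resident_equilibrium(m, 0)
  ## calibration restated: plateau within 2% of target
  expect_lt(abs(res$density - attr(m, "plateau_target")), 0.02 * 2)
  expect_equal(res$lambda, 1, tolerance = 1e-9)
  ## one more step changes density below tolerance
  A <- build_annual_matrix(m, density = res$density)
  v2 <- as.numeric(A %*% res$structure)
  expect_lt(abs(sum(v2) / m$area - res$density), 1e-8)

  ## two different founders reach the same stationary structure
  f1 <- rep(0, m$space$n); f1[which(m$space$states$name == "V1>V1")] <- 1
  f2 <- rep(0, m$space$n); f2[which(m$space$states$name == "D>V2")] <- 5
  r1 <- resident_equilibrium(m, 0, method = "iterate", founder = f1)
  r2 <- resident_equilibrium(m, 0, method = "iterate", founder = f2)
  expect_lt(max(abs(r1$structure / sum(r1$structure) -
                      r2$structure / sum(r2$structure))), 1e-6)

  ## an unviable resident raises an equilibrium error
  dead <- m; dead$fec$germination <- 1e-6
  expect_error(resident_equilibrium(dead, 0),
               class = "sproutess_equilibrium_error")
})

test_that("invasion fitness is neutral on the diagonal and matches the eigen oracle", {
  for (a in c("cypripedium", "ophrys", "ophrys_age")) {
    m <- cached_fixture(a)
    set.seed(11)
    for (d in runif(4, -0.4, 0.4)) {
      res <- resident_equilibrium(m, d)
      f <- invasion_fitness(m, d, d, resident = res)
      expect_lt(abs(f$fitness), 1e-8)
      dm <- d + 0.3
      fm <- invasion_fitness(m, d, dm, resident = res)
      oracle <- log(dominant_lambda(
        build_annual_matrix(m, d_spr = dm, density = res$density)))
      expect_lt(abs(fm$fitness - oracle), 1e-6)
    }
  }
})

test_that("stochastic invasion fitness is seed-reproducible and near the deterministic value", {
  m <- cached_fixture("cypripedium")
  res <- resident_equilibrium(m, 0)
  f1 <- invasion_fitness(m, 0, 0.3, steps = 40, mode = "stochastic",
                         seed = 5, resident = res)
  f2 <- invasion_fitness(m, 0, 0.3, steps = 40, mode = "stochastic",
                         seed = 5, resident = res)
  expect_identical(f1$fitness, f2$fitness)
  f3 <- invasion_fitness(m, 0, 0.3, steps = 40, mode = "stochastic",
                         seed = 6, resident = res)
  expect_false(identical(f1$fitness, f3$fitness))
})

test_that("the invasibility grid is neutral on its diagonal with a coherent sign pattern", {
  m <- cached_fixture("cypripedium")
  g <- pip(m, d_range = c(-0.45, 0.25), resolution = 8)
  expect_true(all(abs(diag(g$fitness)) < 1e-8))
  ## the fixture optimum lies inside the grid: each resident column of the
  ## fitness landscape favours mutants on the side of the optimum
  est <- find_ess(m, bounds = c(-1, 1))
  jstar <- which.min(abs(g$d_values - est$d_star))
  ## a mutant at (approximately) the ESS invades every non-ESS resident
  for (i in seq_along(g$d_values)) {
    if (abs(g$d_values[i] - est$d_star) < 0.05) next
    expect_gt(g$fitness[i, jstar], 0)
  }
  f <- tempfile(fileext = ".csv")
  write_pip_csv(g, f)
  expect_equal(nrow(read.csv(f, check.names = FALSE)), 8)
})

test_that("the located ESS is convergence-stable and locally dominant", {
  m <- cached_fixture("cypripedium")
  est <- find_ess(m, bounds = c(-1, 1))
  expect_true(est$convergence_stable)
  expect_true(est$local_max)
  expect_lt(abs(est$gradient), 1e-3)
  ## local strategy dominance: no nearby mutant beats the ESS resident
  res <- resident_equilibrium(m, est$d_star)
  f0 <- invasion_fitness(m, est$d_star, est$d_star, resident = res)$fitness
  for (dm in est$d_star + seq(-0.3, 0.3, by = 0.1)) {
    fm <- invasion_fitness(m, est$d_star, dm, resident = res)$fitness
    expect_lte(fm, f0 + 1e-6)
  }
  ## refinement consistency: a doubled-resolution grid brackets the same ESS
  g1 <- pip(m, d_range = c(-0.4, 0.2), resolution = 7)
  g2 <- pip(m, d_range = c(-0.4, 0.2), resolution = 13)
  sign_flip <- function(g) {
    gr <- sapply(seq_along(g$d_values), function(i) {
      j <- max(i - 1, 1); k <- min(i + 1, length(g$d_values))
      g$fitness[i, k] - g$fitness[i, j]
    })
    g$d_values[which(diff(sign(gr)) != 0)[1]]
  }
  expect_lt(abs(sign_flip(g1) - est$d_star), 0.11)  # one coarse cell
  expect_lt(abs(sign_flip(g2) - est$d_star), 0.06)

  ## non-bracketing bounds raise a no-ESS error
  expect_error(find_ess(m, bounds = c(0.5, 1.2)), class = "sproutess_no_ess")
})

test_that("warming shifts the Cypripedium-analogue optimum upward", {
  m <- cached_fixture("cypripedium")
  base <- find_ess(m, bounds = c(-1, 1))$d_star
  warm <- find_ess(set_model_climate(m, c(frost_tp1 = -2)),
                   bounds = c(-1, 1.5))$d_star
  expect_gt(warm, base)
})

test_that("the ESS bootstrap is seeded, hierarchical and reports failures", {
  m <- cached_fixture("cypripedium")
  truth <- attr(m, "truth")
  truth$n0 <- 400; truth$n_years <- 14
  cl <- gen_climate_series(16, list(frost = list(mean = 0, sd = 1),
                                    precip = list(mean = 0, sd = 1)),
                           seed = 2, start_year = 0)
  tab <- simulate_individuals(truth, cl, seed = 31)
  config <- list(
    design = "historical", space = m$space, fec = m$fec, area = m$area,
    dd_rate = "sprouting", plateau_target = attr(m, "plateau_target"),
    climate_spec = m$climate_spec,
    rates = list(
      survival = list(terms = names(m$specs$survival$coef)[-1]),
      sprouting = list(terms = "siz_t"),
      growth = list(terms = "siz_t"),
      flowering = list(terms = "siz_target"),
      flowercount = list(terms = "siz_t")))
  ## some resamples legitimately lose population viability and are
  ## excluded; the reliability warning is exercised explicitly below
  b1 <- suppressWarnings(
    bootstrap_ess(tab, cl, config, B = 5, seed = 17, bounds = c(-2, 2)))
  b2 <- suppressWarnings(
    bootstrap_ess(tab, cl, config, B = 5, seed = 17, bounds = c(-2, 2)))
  expect_identical(b1$se, b2$se)
  expect_gte(b1$se, 0)
  expect_lt(b1$n_fail, 5)
  expect_gte(sum(is.finite(b1$estimates)), 3)
  expect_error(bootstrap_ess(tab, cl, config, B = 1),
               class = "sproutess_invalid_argument")

  ## a dataset too small to refit reliably triggers the reliability warning
  tiny <- tab[tab$id %in% unique(tab$id)[1:25], ]
  class(tiny) <- class(tab); attr(tiny, "design") <- attr(tab, "design")
  expect_warning(bootstrap_ess(tiny, cl, config, B = 3, seed = 1,
                               bounds = c(-2, 2)),
                 class = "sproutess_bootstrap_unreliable")
})
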