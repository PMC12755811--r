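test_that("FBA recovers forced flux through a single pathway", {
  sol <- fba(chain_model(uptake = 10))
  expect_identical(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 1.0, tolerance = 1e-9)
  expect_equal(unname(fluxes(sol)[["EX_a"]]), -10, tolerance = 1e-9)
})

test_that("an unsatisfiable maintenance demand is reported infeasible", {
  rx <- rbind(
    simple_reaction("EX_a", c(a_e = -1), 0, 1000, kind = "exchange"),
    simple_reaction("ATPM", c(a = -1), 1, 1000, kind = "pseudo"))
  m <- MetabolicModel(rx, simple_metabolites("a", "a_e"),
                      objectiveReaction = "ATPM")
  sol <- fba(m)
  expect_identical(solverStatus(sol), "infeasible")
  expect_true(is.na(objectiveValue(sol)))
})

test_that("FBA growth on the synthetic models matches scipy HiGHS", {
  for (m in list(native_model(), recombinant_model())) {
    S <- as.matrix(stoichiometricMatrix(m, sparse = FALSE))
    b <- bounds(m)
    j <- match(objectiveReaction(m), b$reaction)
    res <- scipy_lp_batch(list(list(S = S, lb = b$lb, ub = b$ub, obj = j)))
    expect_true(res[[1]]$ok)
    expect_equal(objectiveValue(fba(m)), res[[1]]$val, tolerance = 1e-6)
  }
})

test_that("optimal flux distributions satisfy steady state and bounds", {
  for (m in list(native_model(), recombinant_model())) {
    sol <- fba(m)
    v <- fluxes(sol)
    S <- as.matrix(stoichiometricMatrix(m, sparse = FALSE))
    expect_lt(max(abs(S %*% v)), 1e-6)
    b <- bounds(m)
    expect_true(all(v >= b$lb - 1e-9 & v <= b$ub + 1e-9))
  }
})

test_that("relaxing a bound never decreases a maximization optimum", {
  m <- native_model()
  base <- objectiveValue(fba(m))
  b <- bounds(m)
  set.seed(11)
  for (k in 1:10) {
    i <- sample(nrow(b), 1)
    m2 <- m
    bounds(m2, b$reaction[i]) <- c(b$lb[i] - 5, b$ub[i] + 5)
    sol <- fba(m2)
    expect_identical(solverStatus(sol), "optimal")
    expect_gte(objectiveValue(sol), base - 1e-6)
  }
})

test_that("fixGrowthFraction pins growth and relaxes monotonically", {
  r <- recombinant_model()
  mu <- objectiveValue(fba(r))
  ## fraction 1: maximizing HA afterwards keeps growth at the optimum
  m1 <- fixGrowthFraction(r, 1.0)
  ha1 <- fba(m1, objective = "EX_ha_e")
  expect_equal(unname(fluxes(ha1)[["BIOMASS"]]), mu, tolerance = 1e-6)
  ## fraction 0.95 is a relaxation: HA optimum cannot shrink
  m95 <- fixGrowthFraction(r, 0.95)
  ha95 <- fba(m95, objective = "EX_ha_e")
  expect_gte(objectiveValue(ha95), objectiveValue(ha1) - 1e-9)
})

test_that("95%-growth product optimum matches a bilevel grid search", {
  r <- recombinant_model()
  mu <- objectiveValue(fba(r))
  m95 <- fixGrowthFraction(r, 0.95)
  ha95 <- objectiveValue(fba(m95, objective = "EX_ha_e"))
  ## brute force: sweep fixed growth values across [0.95, 1] mu and take
  ## the best product optimum
  grid <- seq(0.95, 1, length.out = 21) * mu
  best <- max(vapply(grid, function(g) {
    m2 <- r
    bounds(m2, "BIOMASS") <- c(g, g)
    sol <- fba(m2, objective = "EX_ha_e")
    if (solverStatus(sol) == "optimal") objectiveValue(sol) else -Inf
  }, 0))
  expect_equal(ha95, best, tolerance = 1e-6)
})

test_that("robustness analysis equals pointwise FBA and responds to oxygen", {
  m <- native_model()
  ## one grid point at the current bound reproduces plain FBA
  b <- bounds(m)
  o2lb <- b$lb[b$reaction == "EX_o2_e"]
  one <- robustnessAnalysis(m, "EX_ha_e", "EX_o2_e", o2lb)
  expect_equal(one$objective,
               objectiveValue(fba(m, objective = "EX_ha_e")),
               tolerance = 1e-9)
  ## a 5-point grid equals 5 independent FBA calls
  grid <- seq(0, -20, by = -5)
  curve <- robustnessAnalysis(m, "EX_ha_e", "EX_o2_e", grid)
  manual <- vapply(grid, function(g) {
    m2 <- m
    bounds(m2, "EX_o2_e") <- c(g, 1000)
    objectiveValue(fba(m2, objective = "EX_ha_e"))
  }, 0)
  expect_equal(curve$objective, manual[order(grid)], tolerance = 1e-9)
  ## more oxygen allowance never lowers the HA optimum
  expect_true(all(diff(curve$objective) <= 1e-9))
})

test_that("chemostat flux follows the dilution-rate formula", {
  expect_equal(chemostatFlux(0.3, 12, 2, 2), 1.5)
  expect_equal(chemostatFlux(0.5, 7, 7, 3), 0)
  expect_equal(chemostatFlux(0.4, 0, 20, 1), -8)   # uptake is negative
  expect_error(chemostatFlux(0.4, 1, 0, 0), "positive")
  expect_error(chemostatFlux(-0.1, 1, 0, 1), "non-negative")
})

test_that("rescaling to a reference uptake preserves steady state", {
  m <- native_model()
  sol <- fba(m)
  scaled <- rescaleToUptake(sol, "EX_glc__D_e", 100)
  expect_equal(unname(fluxes(scaled)[["EX_glc__D_e"]]), -100,
               tolerance = 1e-9)
  f <- 100 / abs(fluxes(sol)[["EX_glc__D_e"]])
  expect_equal(fluxes(scaled), fluxes(sol) * f, tolerance = 1e-12)
  S <- as.matrix(stoichiometricMatrix(m, sparse = FALSE))
  expect_lt(max(abs(S %*% fluxes(scaled))), 1e-6)
  ## zero uptake cannot anchor a scaling
  expect_error(rescaleToUptake(sol, "EX_fru_e"), "zero")
})

test_that("ATP yield reflects fermentative vs respiring catabolism", {
  ## EMP-only toy: 2 ATP per glucose by substrate-level phosphorylation
  rx <- rbind(
    simple_reaction("EX_glc", c(glc_e = -1), -1, 1000, kind = "exchange"),
    simple_reaction("EX_lac", c(lac_e = -1), 0, 1000, kind = "exchange"),
    simple_reaction("EMP",
      c(glc_e = -1, adp = -2, pi = -2, lac_e = 2, atp = 2, h2o = 2),
      0, 1000),
    simple_reaction("ATPM", c(atp = -1, h2o = -1, adp = 1, pi = 1),
                    0, 1000, kind = "pseudo"),
    simple_reaction("GROWTH", c(atp = -1, h2o = -1, adp = 1, pi = 1),
                    0, 1000, kind = "pseudo"))
  toy <- MetabolicModel(rx,
    simple_metabolites(c("atp", "adp", "pi", "h2o"),
                       c("glc_e", "lac_e")),
    objectiveReaction = "GROWTH")
  expect_equal(atpYieldPerGlucose(toy, "EX_glc", "ATPM"), 2,
               tolerance = 1e-9)
  ## respiring recombinant out-yields the fermentative native producer
  y_nat <- atpYieldPerGlucose(native_model())
  y_rec <- atpYieldPerGlucose(recombinant_model())
  expect_gt(y_rec, y_nat)
  ## yield is intensive: doubling the allowed uptake does not change it
  m2 <- native_model()
  bounds(m2, "EX_glc__D_e") <- c(-2 * 18.56, 1000)
  expect_equal(atpYieldPerGlucose(m2), y_nat, tolerance = 1e-9)
})
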