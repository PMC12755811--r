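test_that("search returns nothing when no deletion can raise the product", {
  ## single forced pathway: every knockout only destroys flux
  m <- chain_model()
  m@genes <- c("gT")
  m@reactions$gpr[2] <- "gT"
  cfg <- searchConfig("EX_a", maxDepth = 1)
  res <- iterativeKnockoutSearch(m, cfg)
  expect_equal(nrow(res), 0)
})

test_that("search matches exhaustive enumeration on a small gene set", {
  ## restrict the native model to a 10-gene effective search space by
  ## pre-deleting nothing and comparing against brute force over all
  ## 1- and 2-gene knockout combinations evaluated the same way
  m <- aerobic_native()
  ref <- aerobic_reference()
  genes10 <- c("asd_syn", "ilvE_syn", "asnA_syn", "pyrD_syn", "ppc_syn",
               "ldh_syn", "nox_syn", "upp_syn", "alaT_syn", "gdhA_syn")
  m10 <- m
  m10@genes <- genes10
  m10@reactions$gpr <- ifelse(
    vapply(m10@reactions$gpr, function(g)
      length(gprGenes(g)) > 0 && all(gprGenes(g) %in% genes10), TRUE),
    m10@reactions$gpr, "")
  cfg <- searchConfig("EX_ha_e", maxDepth = 2)
  res <- iterativeKnockoutSearch(m10, cfg)

  ref10 <- referenceState(m10)
  p_wt <- fluxes(ref10)[["EX_ha_e"]]
  pheno <- function(ko) {
    sol <- moma(knockout(m10, ko), ref10)
    if (solverStatus(sol) != "optimal") return(c(0, 0))
    c(max(fluxes(sol)[["BIOMASS"]], 0), fluxes(sol)[["EX_ha_e"]])
  }
  improves <- function(p, parent) if (parent > 1e-6)
    p >= parent * 1.01 else p > 1e-6
  ## brute force round 1
  r1 <- lapply(sort(genes10), pheno)
  names(r1) <- sort(genes10)
  keep1 <- names(r1)[vapply(r1, function(x) improves(x[2], p_wt), TRUE)]
  expect_setequal(res$knockouts[res$round == 1], keep1)
  ## brute force round 2 seeded by round-1 survivors of the growth rule
  mu10 <- objectiveValue(fba(m10))
  expand1 <- keep1[vapply(keep1, function(g) r1[[g]][1] >= 0.6 * mu10,
                          TRUE)]
  expected2 <- character(0)
  seen <- keep1
  for (g in expand1) {
    for (h in setdiff(sort(genes10), g)) {
      key <- paste(sort(c(g, h)), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      ph <- pheno(c(g, h))
      if (improves(ph[2], r1[[g]][2]))
        expected2 <- c(expected2, paste(g, h, sep = ","))
    }
  }
  expect_setequal(res$knockouts[res$round == 2], expected2)
})

test_that("every native strategy trades growth for product", {
  m <- aerobic_native()
  cfg <- searchConfig("EX_ha_e", maxDepth = 2)
  res <- iterativeKnockoutSearch(m, cfg)
  expect_gt(nrow(res), 0)
  ref <- aerobic_reference()
  mu <- objectiveValue(ref)
  p_wt <- fluxes(ref)[["EX_ha_e"]]
  expect_true(all(res$productRate > p_wt + 1e-6))
  expect_true(all(res$growth < mu - 1e-6))
  ## multi-round strategies exist and include known precursor drains
  expect_true(any(res$round == 2))
  expect_true(any(grepl("asd_syn", res$knockouts)))
  ## a severe round-one growth loser is reported but never seeds round
  ## two (though it may still join as a second knockout)
  expect_false(any(res$round == 2 & grepl("^ppc_syn,", res$knockouts)))
  ## reported phenotypes are reproducible by independent knockout + MOMA
  for (k in c(1, nrow(res))) {
    ko <- strsplit(res$knockouts[k], ",")[[1]]
    sol <- moma(knockout(m, ko), ref)
    expect_equal(res$growth[k], max(fluxes(sol)[["BIOMASS"]], 0),
                 tolerance = 1e-6)
    expect_equal(res$productRate[k], unname(fluxes(sol)[["EX_ha_e"]]),
                 tolerance = 1e-6)
  }
  ## determinism: a rerun reproduces the table exactly
  res2 <- iterativeKnockoutSearch(m, cfg)
  expect_identical(res, res2)
})

test_that("alternate optima collapse to one point when the optimum is unique", {
  m <- chain_model()
  cfg <- altOptimaConfig(nSamples = 5, seed = 3)
  samples <- sampleAlternateOptima(m, "EX_a", cfg, "max")
  base <- fluxes(samples[[1]])
  for (s in samples) expect_equal(fluxes(s), base, tolerance = 1e-9)
})

test_that("alternate-optima samples respect growth and objective pins", {
  r <- recombinant_model()
  cfg <- altOptimaConfig(nSamples = 20, seed = 7)
  mu <- objectiveValue(fba(r))
  for (dir in c("max", "min")) {
    samples <- sampleAlternateOptima(r, "EX_ha_e", cfg, dir)
    zstar <- attr(samples, "extremeValue")
    S <- as.matrix(stoichiometricMatrix(r, sparse = FALSE))
    for (s in samples) {
      v <- fluxes(s)
      expect_gte(v[["BIOMASS"]], 0.95 * mu - 1e-6)
      expect_lt(abs(v[["EX_ha_e"]] - zstar), 1e-6)
      expect_lt(max(abs(S %*% v)), 1e-6)
    }
  }
  ## the plain FBA vertex at the same constraints lies inside the
  ## sampled flux ranges
  m95 <- fixGrowthFraction(r, 0.95)
  vert <- fba(m95, objective = "EX_ha_e")
  samples <- sampleAlternateOptima(r, "EX_ha_e", cfg, "max")
  M <- vapply(samples, fluxes, fluxes(vert))
  lo <- apply(M, 1, min); hi <- apply(M, 1, max)
  v <- fluxes(vert)
  expect_true(all(v >= lo - 1e-5 & v <= hi + 1e-5))
  ## seeded sampling is reproducible
  again <- sampleAlternateOptima(r, "EX_ha_e", cfg, "max")
  expect_equal(lapply(samples, fluxes), lapply(again, fluxes))
})

test_that("regulation targets separate max- from min-product flux ranges", {
  ## identical sample sets nominate nothing
  m <- chain_model()
  cfg <- altOptimaConfig(nSamples = 3, seed = 1)
  s1 <- sampleAlternateOptima(m, "EX_a", cfg, "max")
  expect_equal(nrow(regulationTargets(s1, s1)), 0)
  ## hand-built two-sample sets with one separated reaction
  mk <- function(vals) FluxDistribution(
    c(R1 = vals[1], R2 = vals[2]), vals[1], "optimal")
  up <- list(mk(c(5, 1)), mk(c(6, 0)))
  dn <- list(mk(c(1, 1)), mk(c(2, 0)))
  tg <- regulationTargets(up, dn)
  expect_identical(tg$reaction, "R1")
  expect_identical(tg$direction, "up")
  expect_equal(tg$separation, 3)  # min(5,6) - max(1,2)
})

test_that("the hyaluronan synthase analog is an up-regulation target", {
  r <- recombinant_model()
  cfg <- altOptimaConfig(nSamples = 20, seed = 7)
  mx <- sampleAlternateOptima(r, "EX_ha_e", cfg, "max")
  mn <- sampleAlternateOptima(r, "EX_ha_e", cfg, "min")
  tg <- regulationTargets(mx, mn)
  expect_true("HAS" %in% tg$reaction)
  expect_identical(tg$direction[tg$reaction == "HAS"], "up")
})

test_that("deleting the oxidative-PPP analog redirects carbon to HA", {
  r <- recombinant_model()
  ref <- referenceState(r)
  ## the wild-type optimum routes flux through G6P dehydrogenase
  expect_gt(fluxes(ref)[["ZWF"]], 1e-6)
  mo <- moma(knockout(r, "zwf_syn"), ref)
  expect_identical(solverStatus(mo), "optimal")
  expect_gt(fluxes(mo)[["EX_ha_e"]], fluxes(ref)[["EX_ha_e"]] + 1e-6)
  expect_lt(fluxes(mo)[["BIOMASS"]], objectiveValue(ref) - 1e-6)
})
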