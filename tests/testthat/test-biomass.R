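test_that("DNA composition uses double-strand base pairing", {
  expect_equal(unname(dnaComposition("ATGC")), rep(0.25, 4),
               ignore_attr = TRUE)
  ## a single all-A strand still implies half dT on the complement
  comp <- dnaComposition("AAAAAA")
  expect_equal(comp[["dAMP"]], 0.5)
  expect_equal(comp[["dTMP"]], 0.5)
  expect_equal(comp[["dCMP"]], 0)
  expect_error(dnaComposition(""), "empty|no unambiguous")
  ## ambiguous bases are skipped and counted
  comp2 <- dnaComposition("ATGCNN")
  expect_equal(attr(comp2, "ambiguous"), 2)
  expect_equal(sum(comp2), 1)
})

test_that("1 kb random genome matches an independent base count", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  comp <- dnaComposition(seq)
  chars <- strsplit(seq, "")[[1]]
  a <- sum(chars == "A"); t <- sum(chars == "T")
  g <- sum(chars == "G"); c <- sum(chars == "C")
  expect_equal(comp[["dAMP"]], (a + t) / 2000)
  expect_equal(comp[["dGMP"]], (g + c) / 2000)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
})

test_that("protein composition translates CDSs and codon tables", {
  comp <- proteinComposition("ATGAAA")
  expect_equal(comp[["met__L"]], 0.5)
  expect_equal(comp[["lys__L"]], 0.5)
  ## codon table with a single codon
  expect_equal(unname(proteinComposition(c(GGT = 12))), 1)
  expect_identical(names(proteinComposition(c(GGT = 12))), "gly")
  ## internal stops skip the CDS with a warning; trailing stops drop
  expect_warning(
    comp2 <- proteinComposition(c("ATGTAAAAA", "ATGGCTTAA")),
    "internal stop")
  expect_setequal(names(comp2), c("met__L", "ala__L"))
  expect_error(proteinComposition(c(XXX = 1)), "invalid codon")
  expect_error(proteinComposition("ATGA"), "divisible")
})

test_that("random CDS translation matches an independent translator", {
  set.seed(8)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  cds <- vapply(1:10, function(i)
    paste(c("ATG", sample(sense, 30, TRUE)), collapse = ""), "")
  comp <- proteinComposition(cds)
  ## oracle: translate by direct table lookup, no Biostrings
  code <- setNames(as.character(Biostrings::GENETIC_CODE), codons)
  tally <- table(unlist(lapply(cds, function(s) {
    trip <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    code[trip]
  })))
  tally <- tally[names(tally) != "*"]
  frac <- as.numeric(tally) / sum(tally)
  map <- c(A = "ala__L", R = "arg__L", N = "asn__L", D = "asp__L",
           C = "cys__L", Q = "gln__L", E = "glu__L", G = "gly",
           H = "his__L", I = "ile__L", L = "leu__L", K = "lys__L",
           M = "met__L", F = "phe__L", P = "pro__L", S = "ser__L",
           T = "thr__L", W = "trp__L", Y = "tyr__L", V = "val__L")
  names(frac) <- map[names(tally)]
  expect_equal(comp[sort(names(frac))], frac[sort(names(frac))],
               tolerance = 1e-12)
})

test_that("assembled biomass carries composition and GAM stoichiometry", {
  comp <- list(
    protein = proteinComposition(c("ATGAAAGCT")),   # M, K, A
    dna = dnaComposition("ATGC"),
    massFractions = c(protein = 0.55, dna = 0.03))
  bm <- assembleBiomass(comp, maintenanceParameters(gam = 39.4))
  st <- bm$reaction$stoichiometry[[1]]
  ## GAM term: 39.4 ATP hydrolyzed per gram biomass
  expect_equal(unname(st[["atp_c"]]), -39.4)
  expect_equal(unname(st[["adp_c"]]), 39.4)
  expect_equal(unname(st[["pi_c"]]), 39.4)
  ## consumed mass equals the declared mass fractions within 1%
  expect_equal(bm$massCheck, 0.58, tolerance = 0.01)
  ## protein-only composition drains only amino acids (plus GAM)
  bm2 <- assembleBiomass(list(
    protein = proteinComposition("ATGAAA"),
    massFractions = c(protein = 1)), maintenanceParameters())
  prec <- setdiff(names(bm2$reaction$stoichiometry[[1]]),
                  c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c"))
  expect_setequal(prec, c("met__L_c", "lys__L_c"))
  expect_equal(bm2$massCheck, 1, tolerance = 0.01)
})

test_that("NGAM reaction pins maintenance flux and taxes growth", {
  rx <- ngamReaction(maintenanceParameters(ngam = 0))
  expect_equal(rx$lb, 0)
  expect_equal(ngamFromMaintenanceUptake(1, 2), 2)
  expect_equal(ngamFromMaintenanceUptake(0.5, 3), 1.5)
  ## growth strictly decreases as NGAM rises in the native model
  mus <- vapply(c(0, 2, 6, 12), function(ng) {
    objectiveValue(fba(makeNativeModel(
      syntheticModelParams(ngam = ng))))
  }, 0)
  expect_true(all(diff(mus) < -1e-6))
})

test_that("the HA route costs 5 ATP, 1 acetyl-CoA and 2 NAD per unit", {
  for (m in list(native_model(), recombinant_model())) {
    ha <- haPathway(m)
    expect_equal(ha$cost$atp_equivalents, 5, tolerance = 1e-9)
    expect_equal(ha$cost$acetyl_coa, 1, tolerance = 1e-9)
    expect_equal(ha$cost$nad, 2, tolerance = 1e-9)
    expect_identical(ha$condensation, "HAS")
    expect_identical(ha$exchange, "EX_ha_e")
  }
  ## the condensation reaction is elementally balanced
  tab <- checkBalance(native_model(), "HAS")
  expect_identical(tab$status, "balanced")
})

test_that("HA cost report equals a stoichiometric path-walk oracle", {
  m <- native_model()
  ha <- haPathway(m)
  rx <- reactions(m)
  route <- c(GLCt = 2, GLK = 2, PGI = 1, PGMT = 1, GALU = 1, UDPGD = 1,
             GLMS = 1, GNA1 = 1, PGAMT = 1, GLMU = 1, HAS = 1)
  net <- numeric(0)
  for (r in names(route)) {
    st <- rx$stoichiometry[[match(r, rx$id)]] * route[[r]]
    for (mm in names(st))
      net[mm] <- (if (mm %in% names(net)) net[[mm]] else 0) + st[[mm]]
  }
  consumed <- function(x) if (x %in% names(net)) max(-net[[x]], 0) else 0
  expect_equal(ha$cost$atp_equivalents,
               consumed("atp_c") + consumed("utp_c") +
               consumed("gln__L_c"))
  expect_equal(ha$cost$acetyl_coa, consumed("accoa_c"))
  expect_equal(ha$cost$nad, consumed("nad_c"))
  ## a model without the precursor branch is rejected
  broken <- m
  broken@reactions <- broken@reactions[broken@reactions$id != "GALU", ]
  expect_error(haPathway(broken), "missing reaction")
})

test_that("HA flux is stoichiometrically coupled to UDP-glucuronate use", {
  m <- fixGrowthFraction(native_model(), 0.95)
  sol <- fba(m, objective = "EX_ha_e")
  v <- fluxes(sol)
  ## each HA unit condenses exactly one UDP-GlcA
  expect_gt(v[["HAS"]], 1e-6)
  expect_equal(unname(v[["HAS"]]), unname(v[["UDPGD"]]), tolerance = 1e-6)
  expect_equal(unname(v[["HAS"]]), unname(v[["EX_ha_e"]]), tolerance = 1e-6)
})
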