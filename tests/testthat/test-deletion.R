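test_that("knockout silences reactions exactly when GPR logic fails", {
  rx <- rbind(
    simple_reaction("EX_a", c(a_e = -1), -10, 1000, kind = "exchange"),
    simple_reaction("At", c(a_e = -1, a = 1), 0, 1000,
                    gpr = "(g1 and g2) or g3", kind = "transport"),
    simple_reaction("GROWTH", c(a = -1), 0, 1000, kind = "pseudo"))
  m <- MetabolicModel(rx, simple_metabolites("a", "a_e"),
                      genes = c("g1", "g2", "g3", "g4"),
                      objectiveReaction = "GROWTH")
  ## complex partner lost but isozyme remains: reaction stays active
  b1 <- bounds(knockout(m, "g1"))
  expect_equal(b1$ub[b1$reaction == "At"], 1000)
  ## complex + isozyme both lost: reaction disabled
  b2 <- bounds(knockout(m, c("g1", "g3")))
  expect_equal(b2[b2$reaction == "At", c("lb", "ub")],
               data.frame(lb = 0, ub = 0), ignore_attr = TRUE)
  ## a gene outside every GPR changes nothing
  expect_equal(bounds(knockout(m, "g4")), bounds(m))
  expect_error(knockout(m, "nope"), "unknown gene")
})

test_that("knockout is idempotent", {
  m <- native_model()
  k1 <- knockout(m, c("asd_syn", "tktA_syn"))
  k2 <- knockout(k1, c("asd_syn", "tktA_syn"))
  expect_equal(bounds(k1), bounds(k2))
})

test_that("single-gene screen finds lethal, sick and neutral classes", {
  m <- native_model()
  screen <- native_singles()
  sr <- setNames(screen$Rgr, screen$gene)
  ## the sole enolase gene blocks glycolysis completely
  expect_identical(
    screen$class[screen$gene == "eno_syn"], "lethal")
  expect_lt(sr[["eno_syn"]], 1e-6)
  ## one transketolase isozyme is fully covered by the other
  expect_identical(screen$class[screen$gene == "tktA_syn"], "neutral")
  expect_equal(sr[["tktA_syn"]], 1, tolerance = 1e-6)
  ## all three classes occur in the native network
  expect_setequal(unique(screen$class), c("lethal", "sick", "neutral"))
})

test_that("screen Rgr values match fresh per-gene recomputation", {
  m <- native_model()
  screen <- native_singles()
  mu <- objectiveValue(fba(m))
  set.seed(9)
  for (g in sample(screen$gene, 8)) {
    sol <- fba(knockout(m, g))
    growth <- if (solverStatus(sol) == "optimal")
      max(objectiveValue(sol), 0) else 0
    expect_equal(screen$Rgr[screen$gene == g], growth / mu,
                 tolerance = 1e-9)
  }
})

test_that("double deletions expose synthetic lethality of isozyme pairs", {
  doubles <- native_doubles()
  pick <- function(a, b) doubles[
    (doubles$gene1 == a & doubles$gene2 == b) |
    (doubles$gene1 == b & doubles$gene2 == a), ]
  ## canonical case: two isozymes of an essential reaction
  tkt <- pick("tktA_syn", "tktB_syn")
  expect_identical(tkt$class, "synthetic_lethal")
  expect_lt(tkt$Rgr, 1e-6)
  singles <- native_singles()
  sr <- setNames(singles$Rgr, singles$gene)
  expect_gt(sr[["tktA_syn"]], 0.99)
  expect_gt(sr[["tktB_syn"]], 0.99)
  ## independent pathways: double equals the worse single, no interaction
  ind <- pick("ldh_syn", "upp_syn")
  expect_identical(ind$class, "no_interaction")
  expect_equal(ind$Rgr, min(sr[["ldh_syn"]], sr[["upp_syn"]]),
               tolerance = 1e-6)
})

test_that("double-deletion growth is nested below both singles", {
  singles <- native_singles()
  doubles <- native_doubles()
  sr <- setNames(singles$Rgr, singles$gene)
  expect_true(all(
    doubles$Rgr <= pmin(sr[doubles$gene1], sr[doubles$gene2]) + 1e-6))
})

test_that("interaction summary percentages match a matrix recount", {
  singles <- native_singles()
  doubles <- native_doubles()
  s <- summarizeInteractions(singles, doubles)
  n <- nrow(singles)
  ## adjacency-matrix recount of interaction degrees
  recount <- function(class) {
    genes <- singles$gene
    A <- matrix(0L, n, n, dimnames = list(genes, genes))
    sel <- doubles$class == class
    for (k in which(sel)) {
      A[doubles$gene1[k], doubles$gene2[k]] <- 1L
      A[doubles$gene2[k], doubles$gene1[k]] <- 1L
    }
    rowSums(A)
  }
  dl <- recount("synthetic_lethal"); ds <- recount("synthetic_sick")
  expect_equal(s$pct_synthetic_lethal_1, 100 * sum(dl == 1) / n)
  expect_equal(s$pct_synthetic_sick_1, 100 * sum(ds == 1) / n)
  expect_equal(s$pct_synthetic_lethal_ge5, 100 * sum(dl >= 5) / n)
  expect_equal(s$pct_synthetic_sick_ge5, 100 * sum(ds >= 5) / n)
  expect_equal(s$pct_lethal, 100 * sum(singles$class == "lethal") / n)
  expect_equal(s$pct_sick, 100 * sum(singles$class == "sick") / n)
  expect_true(all(unlist(s) >= 0 & unlist(s) <= 100))
})

test_that("a hand-built toy summary counts one synthetic-lethal pair", {
  ## 6 genes; g1/g2 are isozymes of the only route, others inert
  rx <- rbind(
    simple_reaction("EX_a", c(a_e = -1), -10, 1000, kind = "exchange"),
    simple_reaction("T1", c(a_e = -1, a = 1), 0, 1000, "g1",
                    kind = "transport"),
    simple_reaction("T2", c(a_e = -1, a = 1), 0, 1000, "g2",
                    kind = "transport"),
    simple_reaction("X1", c(a = -1, b = 1), 0, 1000, "g3 or g4"),
    simple_reaction("X2", c(b = -1, a = 1), 0, 1000, "g5 or g6"),
    simple_reaction("GROWTH", c(a = -1), 0, 1000, kind = "pseudo"))
  m <- MetabolicModel(rx, simple_metabolites(c("a", "b"), "a_e"),
                      genes = paste0("g", 1:6),
                      objectiveReaction = "GROWTH")
  singles <- singleGeneDeletion(m)
  doubles <- doubleGeneDeletion(m, singles = singles)
  s <- summarizeInteractions(singles, doubles)
  expect_equal(s$pct_synthetic_lethal_1, 2 / 6 * 100)
  expect_equal(s$pct_lethal, 0)
  expect_equal(s$pct_synthetic_lethal_ge5, 0)
})

test_that("no interacting pairs means all synthetic percentages are zero", {
  m <- chain_model()
  m@genes <- c("gA", "gB")
  m@reactions$gpr[2] <- "gA or gB"
  singles <- singleGeneDeletion(m)
  doubles <- doubleGeneDeletion(m, singles = singles)
  s <- summarizeInteractions(singles, doubles)
  ## gA/gB are isozymes of the sole transport: that pair IS synthetic
  ## lethal; drop it to exercise the zero case
  doubles$class <- "no_interaction"
  s0 <- summarizeInteractions(singles, doubles)
  expect_equal(s0$pct_synthetic_lethal_1, 0)
  expect_equal(s0$pct_synthetic_sick_1, 0)
  expect_equal(s0$pct_synthetic_lethal_ge5, 0)
  expect_equal(s0$pct_synthetic_sick_ge5, 0)
})
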