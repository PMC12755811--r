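test_that("growth error is the signed relative deviation in percent", {
  ge <- growthError(0.4, 0.3732)
  expect_equal(unname(ge["error"]), 6.7)
  expect_equal(unname(ge["accuracy"]), 93.3)
  expect_equal(unname(growthError(0.7, 0.7)["error"]), 0)
  expect_equal(unname(growthError(1.0, 1.2)["error"]), -20.0)
  expect_error(growthError(0, 0.1), "positive")
})

test_that("confusion metrics reproduce the printed screen tables", {
  ## amino-acid screen counts: 11 TP, 2 FP, 9 TN, 0 FN
  m4 <- confusionMetrics(c(tp = 11, fp = 2, tn = 9, fn = 0))
  expect_equal(unname(m4["precision"]), 84.61)
  expect_equal(unname(m4["accuracy"]), 90.90)
  expect_equal(unname(m4["sensitivity"]), 100)
  expect_equal(unname(m4["specificity"]), 81.81)
  expect_equal(unname(m4["npv"]), 100)
  expect_equal(unname(m4["f_score"]), 91.66)
  ## carbon-source screen: 5 TP, 1 TN, nothing wrong
  m5 <- confusionMetrics(c(tp = 5, fp = 0, tn = 1, fn = 0))
  expect_true(all(m5 == 100))
  ## a perfectly balanced table
  mb <- confusionMetrics(c(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(unname(mb["accuracy"]), 50)
  expect_equal(unname(mb["precision"]), 50)
  ## undefined metrics are NA, not errors
  m0 <- confusionMetrics(c(tp = 0, fp = 0, tn = 3, fn = 0))
  expect_true(is.na(m0[["precision"]]))
  expect_equal(unname(m0[["specificity"]]), 100)
})

test_that("metrics agree with a brute-force label tally for all n <= 4", {
  ## enumerate every experimental/predicted labeling of up to 4 conditions
  for (n in 1:4) {
    grid <- expand.grid(rep(list(c("G", "NG")), 2 * n),
                        stringsAsFactors = FALSE)
    for (row in seq_len(nrow(grid))) {
      e <- unlist(grid[row, 1:n]); p <- unlist(grid[row, n + 1:n])
      screen <- data.frame(condition = paste0("c", 1:n),
                           experimental = e, predicted = p)
      tab <- tallyPhenotypes(screen)
      ## oracle: direct counting
      tp <- sum(e == "G" & p == "G"); fp <- sum(e == "NG" & p == "G")
      tn <- sum(e == "NG" & p == "NG"); fn <- sum(e == "G" & p == "NG")
      expect_equal(unname(tab), c(tp, fp, tn, fn))
      got <- confusionMetrics(tab, printed = FALSE)
      trunc2 <- function(x) trunc(x * 100) / 100
      want <- c(
        precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
        accuracy = 100 * (tp + tn) / n,
        sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
        npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_)
      expect_equal(got[names(want)], want, tolerance = 1e-12)
    }
  }
})

test_that("F-score is the harmonic mean of precision and sensitivity", {
  set.seed(4)
  for (k in 1:20) {
    tab <- c(tp = sample(0:9, 1), fp = sample(0:9, 1),
             tn = sample(0:9, 1), fn = sample(0:9, 1))
    if (sum(tab) == 0) next
    m <- confusionMetrics(tab, printed = FALSE)
    if (is.na(m["precision"]) || is.na(m["sensitivity"]) ||
        m[["precision"]] + m[["sensitivity"]] == 0) next
    hm <- 2 / (1 / m[["precision"]] + 1 / m[["sensitivity"]])
    expect_equal(m[["f_score"]], hm, tolerance = 1e-9)
  }
})

test_that("essentiality screen flags exactly the built-in auxotrophies", {
  m <- native_model()
  nutrients <- c(
    "-His" = "EX_his__L_e", "-Trp" = "EX_trp__L_e",
    "-Phe" = "EX_phe__L_e", "-Tyr" = "EX_tyr__L_e",
    "-Cys" = "EX_cys__L_e", "-Ala" = "EX_ala__L_e",
    "-Asp" = "EX_asp__L_e", "-Asn" = "EX_asn__L_e",
    "-Glu" = "EX_glu__L_e", "-Gln" = "EX_gln__L_e",
    "-Lys" = "EX_lys__L_e", "-Val" = "EX_val__L_e")
  before <- bounds(m)
  screen <- essentialityScreen(m, nutrients)
  ng <- screen$condition[screen$predicted == "NG"]
  expect_setequal(ng, c("-His", "-Trp", "-Phe", "-Tyr", "-Cys"))
  expect_identical(screen$predicted[screen$condition == "complete"], "G")
  ## the input model is untouched
  expect_equal(bounds(m), before)
  expect_error(essentialityScreen(m, c(X = "EX_nope")), "EX_nope")
})

test_that("carbon screen grows on every sugar and starves without one", {
  m <- native_model()
  sources <- c(Glucose = "EX_glc__D_e", Sucrose = "EX_sucr_e",
               Fructose = "EX_fru_e", Maltose = "EX_malt_e",
               Lactose = "EX_lcts_e")
  exp_lab <- c("No sugar" = "NG", Glucose = "G", Sucrose = "G",
               Fructose = "G", Maltose = "G", Lactose = "G")
  screen <- carbonSourceScreen(m, sources, experimental = exp_lab)
  expect_identical(screen$predicted[screen$condition == "No sugar"], "NG")
  expect_true(all(screen$predicted[screen$condition != "No sugar"] == "G"))
  ## perfect agreement with the expected labels
  expect_equal(unname(tallyPhenotypes(screen)), c(5L, 0L, 1L, 0L))
  expect_true(all(confusionMetrics(tallyPhenotypes(screen)) == 100))
})

test_that("model stats compute printed-precision gene coverage", {
  m <- native_model()
  st <- modelStats(m)
  expect_equal(st$genes, length(genes(m)))
  expect_equal(st$reactions, nrow(reactions(m)))
  expect_equal(st$metabolites, nrow(metabolites(m)))
  expect_equal(sum(st$reactions_by_kind), nrow(reactions(m)))
  expect_equal(st$reactions_without_genes,
               sum(!nzchar(reactions(m)$gpr)))
  ## coverage at the printed precision: 522 of 2049 genes reads 25.47
  m2 <- m
  m2@genes <- paste0("g", 1:522)
  m2@reactions$gpr <- ""
  m2@genomeGeneCount <- 2049L
  expect_equal(modelStats(m2)$gene_coverage_pct, 25.47)
  m2@genes <- character(0)
  expect_equal(modelStats(m2)$gene_coverage_pct, 0)
})
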