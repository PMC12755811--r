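## Model validation: growth-rate error, essentiality and carbon-source
## screens, confusion-matrix metrics and model summary statistics.
##
## Reporting convention: percentages are cut (not rounded) to the printed
## precision, matching the truncation used in published validation tables
## (e.g. 11/13 prints as 84.61%, 522/2049 as 25.47%).

## truncate toward zero at `digits` decimals (printed-precision style)
.truncDigits <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits

.GROWTH_TOL <- 1e-6

#' Growth-rate prediction error
#'
#' \code{error = (experimental - predicted) / experimental * 100},
#' signed (negative for overprediction), reported at one decimal;
#' \code{accuracy = 100 - error}.
#'
#' @param experimental measured specific growth rate (1/h), positive.
#' @param predicted model-predicted growth rate (1/h).
#' @return named numeric \code{c(error, accuracy)} in percent.
#' @examples
#' growthError(0.4, 0.3732)  # error 6.7, accuracy 93.3
#' @export
growthError <- function(experimental, predicted) {
  if (any(experimental <= 0))
    stop("experimental growth rate must be positive")
  err <- round((experimental - predicted) / experimental * 100, 1)
  c(error = err, accuracy = 100 - err)
}

#' Derive confusion phenotypes for a screen
#'
#' Growth (G) is the positive class: experimental G predicted G is TP,
#' experimental NG predicted G is FP, and so on.
#'
#' @param screen data.frame with columns \code{experimental} and
#'   \code{predicted} (each "G" or "NG").
#' @return the screen with a \code{phenotype} column (TP/FP/TN/FN).
#' @export
derivePhenotypes <- function(screen) {
  stopifnot(all(c("experimental", "predicted") %in% names(screen)))
  e <- screen$experimental; p <- screen$predicted
  if (!all(c(e, p) %in% c("G", "NG"))) stop("labels must be 'G' or 'NG'")
  screen$phenotype <- ifelse(e == "G" & p == "G", "TP",
                      ifelse(e == "NG" & p == "G", "FP",
                      ifelse(e == "NG" & p == "NG", "TN", "FN")))
  screen
}

#' Tally screen phenotypes into a confusion table
#'
#' @param screen a data.frame with a \code{phenotype} column (or
#'   \code{experimental}/\code{predicted} columns, from which phenotypes
#'   are derived).
#' @return named integer vector \code{c(tp, fp, tn, fn)}.
#' @export
tallyPhenotypes <- function(screen) {
  if (!"phenotype" %in% names(screen)) screen <- derivePhenotypes(screen)
  ph <- factor(screen$phenotype, levels = c("TP", "FP", "TN", "FN"))
  stats::setNames(as.integer(table(ph)), c("tp", "fp", "tn", "fn"))
}

#' Nutrient essentiality screen
#'
#' For each removable nutrient, closes its uptake (exchange lower bound
#' to zero), re-runs FBA on biomass, and records growth (G) or no growth
#' (NG: growth at or below the 1e-6 tolerance); bounds are restored
#' between tests, so the input model is unchanged. A baseline condition
#' with nothing removed is included first.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param removableNutrients named character vector: condition label ->
#'   exchange reaction id.
#' @param experimental optional named character vector of experimental
#'   labels ("G"/"NG") by condition, adding phenotype classification.
#' @param baselineLabel label of the nothing-removed condition.
#' @return data.frame \code{(condition, growth, predicted[,
#'   experimental, phenotype])}.
#' @examples
#' m <- makeNativeModel()
#' essentialityScreen(m, c("-His" = "EX_his__L_e", "-Ala" = "EX_ala__L_e"))
#' @export
essentialityScreen <- function(model, removableNutrients,
                               experimental = NULL,
                               baselineLabel = "complete") {
  rxids <- model@reactions$id
  bad <- setdiff(removableNutrients, rxids)
  if (length(bad))
    stop("nutrient without exchange reaction: ",
         paste(bad, collapse = ", "))
  run <- function(m) {
    sol <- fba(m)
    if (solverStatus(sol) != "optimal") 0 else max(objectiveValue(sol), 0)
  }
  growth <- c(run(model), vapply(removableNutrients, function(ex) {
    m2 <- model
    i <- .rxnIndex(m2, ex)
    m2@reactions$lb[i] <- max(m2@reactions$lb[i], 0)
    run(m2)
  }, 0))
  out <- data.frame(
    condition = c(baselineLabel, names(removableNutrients)),
    growth = unname(growth),
    predicted = ifelse(growth > .GROWTH_TOL, "G", "NG"))
  if (!is.null(experimental)) {
    out$experimental <- unname(experimental[out$condition])
    out <- derivePhenotypes(out)
  }
  out
}

#' Carbon-source utilization screen
#'
#' Tests growth on each carbon source alone: all listed source exchanges
#' are closed, then one at a time is opened at the configured uptake
#' rate and FBA is run on biomass. A "No sugar" condition (all sources
#' closed) is always included. The input model is not modified.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param sources named character vector: source label -> exchange
#'   reaction id (include the reference sugar, e.g. glucose).
#' @param uptakeRate uptake bound applied to the open source
#'   (mmol/gDCW/h, default 18.56).
#' @param experimental optional named character vector of experimental
#'   labels ("G"/"NG"), including "No sugar".
#' @return data.frame \code{(condition, growth, predicted[,
#'   experimental, phenotype])}.
#' @examples
#' m <- makeNativeModel()
#' src <- c(Glucose = "EX_glc__D_e", Fructose = "EX_fru_e")
#' carbonSourceScreen(m, src)
#' @export
carbonSourceScreen <- function(model, sources, uptakeRate = 18.56,
                               experimental = NULL) {
  rxids <- model@reactions$id
  bad <- setdiff(sources, rxids)
  if (length(bad))
    stop("carbon source without exchange reaction: ",
         paste(bad, collapse = ", "))
  closed <- model
  for (ex in sources) {
    i <- .rxnIndex(closed, ex)
    closed@reactions$lb[i] <- max(closed@reactions$lb[i], 0)
  }
  run <- function(m) {
    sol <- fba(m)
    if (solverStatus(sol) != "optimal") 0 else max(objectiveValue(sol), 0)
  }
  growth <- c(run(closed), vapply(sources, function(ex) {
    m2 <- closed
    i <- .rxnIndex(m2, ex)
    m2@reactions$lb[i] <- -abs(uptakeRate)
    run(m2)
  }, 0))
  out <- data.frame(
    condition = c("No sugar", names(sources)),
    growth = unname(growth),
    predicted = ifelse(growth > .GROWTH_TOL, "G", "NG"))
  if (!is.null(experimental)) {
    out$experimental <- unname(experimental[out$condition])
    out <- derivePhenotypes(out)
  }
  out
}

#' Confusion-matrix metrics
#'
#' Computes the standard screen metrics, in percent:
#' precision = TP/(TP+FP), accuracy = (TP+TN)/(TP+FP+TN+FN),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' NPV = TN/(TN+FN), and F-score = 2 * precision * sensitivity /
#' (precision + sensitivity). A metric with a zero denominator is
#' reported as NA rather than failing.
#'
#' @param tab named counts \code{c(tp, fp, tn, fn)}, e.g. from
#'   [tallyPhenotypes()].
#' @param printed cut values to two decimals as printed in validation
#'   tables (default TRUE); set FALSE for full precision.
#' @return named numeric: precision, accuracy, sensitivity,
#'   specificity, npv, f_score (percent).
#' @examples
#' confusionMetrics(c(tp = 11, fp = 2, tn = 9, fn = 0))
#' @export
confusionMetrics <- function(tab, printed = TRUE) {
  tp <- tab[["tp"]]; fp <- tab[["fp"]]; tn <- tab[["tn"]]; fn <- tab[["fn"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- rate(tp, tp + fp)
  sensitivity <- rate(tp, tp + fn)
  f <- if (!is.na(precision) && !is.na(sensitivity) &&
           precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  out <- c(precision = precision,
           accuracy = rate(tp + tn, total),
           sensitivity = sensitivity,
           specificity = rate(tn, tn + fp),
           npv = rate(tn, tn + fn),
           f_score = f)
  if (printed) .truncDigits(out, 2) else out
}

#' Model summary statistics
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return list with gene count, genome coverage percent (two decimals,
#'   printed-precision; NA without a genome gene count), reaction counts
#'   by kind, the number of reactions without known genes, and
#'   metabolite counts by compartment.
#' @examples
#' modelStats(makeNativeModel())
#' @export
modelStats <- function(model) {
  rx <- model@reactions
  ngenes <- length(model@genes)
  coverage <- if (is.na(model@genomeGeneCount)) NA_real_
    else .truncDigits(100 * ngenes / model@genomeGeneCount, 2)
  list(
    genes = ngenes,
    genome_genes = model@genomeGeneCount,
    gene_coverage_pct = coverage,
    reactions = nrow(rx),
    reactions_by_kind = table(factor(rx$kind, levels = .RXN_KINDS)),
    reactions_without_genes = sum(!nzchar(rx$gpr)),
    metabolites = nrow(model@metabolites),
    metabolites_by_compartment = table(
      factor(model@metabolites$compartment, levels = .COMPARTMENTS)))
}
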