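## Strain design: iterative MOMA knockout search and alternate-optima
## comparison for regulation-target nomination.

#' Configuration for the iterative knockout search
#'
#' @param productReaction exchange reaction id of the target product.
#' @param maxDepth maximum number of stacked knockouts (default 3).
#' @param growthDropCutoff fraction of wild-type growth a round-one
#'   candidate may lose and still seed deeper rounds (default 0.40: a
#'   single knockout dropping growth by more than 40 percent is reported
#'   but not expanded).
#' @param improvementThreshold minimum relative product-rate gain over
#'   the parent strain for a deletion to count as improving (default
#'   0.01, i.e. 1 percent).
#' @param method \code{"moma"} (default) or \code{"fba"} for mutant
#'   phenotype prediction.
#' @return a \code{searchConfig} list.
#' @export
searchConfig <- function(productReaction, maxDepth = 3L,
                         growthDropCutoff = 0.40,
                         improvementThreshold = 0.01,
                         method = c("moma", "fba")) {
  stopifnot(growthDropCutoff > 0, growthDropCutoff < 1, maxDepth >= 1L)
  structure(list(productReaction = productReaction,
                 maxDepth = as.integer(maxDepth),
                 growthDropCutoff = growthDropCutoff,
                 improvementThreshold = improvementThreshold,
                 method = match.arg(method)),
            class = "searchConfig")
}

## phenotype (growth, product) of a knockout set
.strainPhenotype <- function(model, geneSet, config, reference) {
  km <- knockout(model, geneSet)
  if (config$method == "moma") {
    sol <- moma(km, reference)
    if (solverStatus(sol) != "optimal") return(c(growth = 0, product = 0))
    v <- fluxes(sol)
  } else {
    sol <- fba(km)
    if (solverStatus(sol) != "optimal") return(c(growth = 0, product = 0))
    v <- fluxes(sol)
  }
  c(growth = max(v[[objectiveReaction(model)]], 0),
    product = v[[config$productReaction]])
}

#' Iterative single-gene-deletion search for product overproduction
#'
#' Round one evaluates every single knockout (MOMA projection of the
#' wild-type reference by default) and keeps deletions that raise the
#' product rate by at least the configured relative threshold. Later
#' rounds repeat single-gene deletion in the genetic background of each
#' surviving mutant, always projecting from the wild-type reference,
#' until \code{maxDepth} knockouts are stacked. A round-one candidate
#' whose growth drops below \code{(1 - growthDropCutoff)} of wild type is
#' reported but not carried into deeper rounds; deeper rounds are not
#' subject to the growth rule.
#'
#' @param model a feasible \linkS4class{MetabolicModel}.
#' @param config a [searchConfig()].
#' @return data.frame of strategies sorted by product rate (descending):
#'   \code{knockouts} (comma-joined, in discovery order), \code{round},
#'   \code{growth}, \code{growthRatioToWild}, \code{productRate}. Empty
#'   when no deletion improves the product rate.
#' @examples
#' m <- makeNativeModel()
#' cfg <- searchConfig("EX_ha_e", maxDepth = 2)
#' head(iterativeKnockoutSearch(m, cfg))
#' @export
iterativeKnockoutSearch <- function(model, config) {
  stopifnot(inherits(config, "searchConfig"))
  .rxnIndex(model, config$productReaction)
  reference <- referenceState(model)
  mu_wt <- objectiveValue(reference)
  if (mu_wt <= .LETHAL_TOL) stop("wild-type model does not grow")
  p_wt <- fluxes(reference)[[config$productReaction]]

  improves <- function(product, parent_product) {
    if (parent_product > .LETHAL_TOL)
      product >= parent_product * (1 + config$improvementThreshold)
    else product > .LETHAL_TOL
  }

  strategies <- list()
  seen <- character(0)
  ## frontier: list of list(genes=, product=) surviving for expansion
  frontier <- list(list(genes = character(0), product = p_wt))
  all_genes <- sort(genes(model))
  for (round in seq_len(config$maxDepth)) {
    next_frontier <- list()
    for (parent in frontier) {
      for (g in setdiff(all_genes, parent$genes)) {
        ko <- c(parent$genes, g)
        key <- paste(sort(ko), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        ph <- .strainPhenotype(model, ko, config, reference)
        if (!improves(ph[["product"]], parent$product)) next
        strategies[[length(strategies) + 1L]] <- data.frame(
          knockouts = paste(ko, collapse = ","),
          round = round,
          growth = ph[["growth"]],
          growthRatioToWild = ph[["growth"]] / mu_wt,
          productRate = ph[["product"]])
        ## the 40% growth rule gates only round-one candidates
        expandable <- round > 1L ||
          ph[["growth"]] >= (1 - config$growthDropCutoff) * mu_wt
        if (expandable && round < config$maxDepth)
          next_frontier[[length(next_frontier) + 1L]] <-
            list(genes = ko, product = ph[["product"]])
      }
    }
    frontier <- next_frontier
    if (length(frontier) == 0L && round < config$maxDepth) break
  }
  if (length(strategies) == 0L)
    return(data.frame(knockouts = character(0), round = integer(0),
                      growth = numeric(0), growthRatioToWild = numeric(0),
                      productRate = numeric(0)))
  out <- do.call(rbind, strategies)
  out <- out[order(-out$productRate, out$knockouts), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Configuration for alternate-optima sampling
#'
#' @param nSamples number of alternate optimal flux distributions
#'   (default 5000).
#' @param growthFraction growth is constrained to at least this fraction
#'   of its optimum (default 0.95).
#' @param seed integer seed for the random secondary objectives.
#' @return an \code{altOptimaConfig} list.
#' @export
altOptimaConfig <- function(nSamples = 5000L, growthFraction = 0.95,
                            seed = 1L) {
  stopifnot(nSamples >= 2L, growthFraction > 0, growthFraction <= 1)
  structure(list(nSamples = as.integer(nSamples),
                 growthFraction = growthFraction,
                 seed = as.integer(seed)),
            class = "altOptimaConfig")
}

#' Sample alternate optima of a production objective
#'
#' Fixes growth to at least \code{growthFraction} of its optimum and the
#' product flux to its extreme (maximum or minimum) value, then scans the
#' remaining optimal face with randomly weighted secondary objectives:
#' each sample is a vertex of the face selected by one random linear
#' objective. With a fixed seed the sample set is fully reproducible.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective product reaction id.
#' @param config an [altOptimaConfig()].
#' @param direction \code{"max"} or \code{"min"}: which extreme of the
#'   product flux the face is anchored at.
#' @return list of \linkS4class{FluxDistribution}, each satisfying the
#'   growth constraint and attaining the extreme product value.
#' @examples
#' m <- makeRecombinantModel()
#' cfg <- altOptimaConfig(nSamples = 10, seed = 7)
#' samples <- sampleAlternateOptima(m, "EX_ha_e", cfg, "max")
#' @export
sampleAlternateOptima <- function(model, objective, config,
                                  direction = c("max", "min")) {
  stopifnot(inherits(config, "altOptimaConfig"))
  direction <- match.arg(direction)
  model <- fixGrowthFraction(model, config$growthFraction)
  ext <- fba(model, objective = objective, direction = direction)
  if (solverStatus(ext) != "optimal")
    stop("growth-constrained model infeasible for product optimization")
  zstar <- objectiveValue(ext)
  bounds(model, objective) <- c(zstar, zstar)
  lp <- .modelLP(model)
  n <- length(lp$ids)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  out <- vector("list", config$nSamples)
  for (k in seq_len(config$nSamples)) {
    w <- stats::runif(n, -1, 1)
    res <- .lpSolve(w, lp$S, numeric(nrow(lp$S)), lp$lb, lp$ub,
                    maximize = TRUE)
    if (res$status != "optimal")
      stop("alternate-optima sample ", k, " failed (", res$status, ")")
    v <- stats::setNames(res$x, lp$ids)
    out[[k]] <- FluxDistribution(v, v[[objective]], "optimal")
  }
  attr(out, "extremeValue") <- zstar
  attr(out, "direction") <- direction
  out
}

#' Nominate up/down-regulation targets from alternate optima
#'
#' Compares the flux ranges a reaction spans across alternate optima of
#' maximized versus minimized product formation. A reaction whose entire
#' max-product flux range lies strictly above its min-product range must
#' carry more flux whenever the product is made -- an up-regulation
#' candidate; the reverse pattern nominates down-regulation. The
#' separation is the gap between the two ranges.
#'
#' @param maxSamples,minSamples lists of \linkS4class{FluxDistribution}
#'   from [sampleAlternateOptima()] with directions "max" and "min", over
#'   the same model.
#' @param tol numeric tolerance for strict separation (default 1e-6).
#' @return data.frame \code{(reaction, direction, separation)} sorted by
#'   separation (descending); zero rows when the sample sets coincide.
#' @export
regulationTargets <- function(maxSamples, minSamples, tol = 1e-6) {
  stopifnot(length(maxSamples) > 0, length(minSamples) > 0)
  ids <- names(fluxes(maxSamples[[1]]))
  if (!identical(ids, names(fluxes(minSamples[[1]]))))
    stop("sample sets cover different reaction sets")
  maxM <- vapply(maxSamples, fluxes, numeric(length(ids)))
  minM <- vapply(minSamples, fluxes, numeric(length(ids)))
  max_lo <- apply(maxM, 1, min); max_hi <- apply(maxM, 1, max)
  min_lo <- apply(minM, 1, min); min_hi <- apply(minM, 1, max)
  up <- max_lo > min_hi + tol
  down <- min_lo > max_hi + tol
  out <- data.frame(
    reaction = c(ids[up], ids[down]),
    direction = c(rep("up", sum(up)), rep("down", sum(down))),
    separation = c((max_lo - min_hi)[up], (min_lo - max_hi)[down]))
  out <- out[order(-out$separation, out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
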