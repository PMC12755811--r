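## Flux balance analysis and derived analyses.

.FEAS_TOL <- 1e-6

## shared: assemble LP pieces from a model
.modelLP <- function(model) {
  list(S = as.matrix(stoichiometricMatrix(model, sparse = FALSE)),
       lb = model@reactions$lb,
       ub = model@reactions$ub,
       ids = model@reactions$id)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady
#' state (S v = 0) and the model bounds, returning one optimal basic
#' solution of the underlying linear program. Degenerate alternate optima
#' exist in most models; reproducibility comes from deterministic solver
#' settings and input ordering, not from uniqueness of the optimum.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objective reaction id to optimize; defaults to the model's
#'   objective (biomass) reaction.
#' @param direction \code{"max"} (default) or \code{"min"}.
#' @return a \linkS4class{FluxDistribution}; \code{solverStatus()} is
#'   \code{"optimal"}, \code{"infeasible"} or \code{"unbounded"} -- never
#'   a silent zero vector.
#' @examples
#' m <- makeNativeModel()
#' sol <- fba(m)
#' objectiveValue(sol)  # predicted growth rate, 1/h
#' @export
fba <- function(model, objective = objectiveReaction(model),
                direction = c("max", "min")) {
  stopifnot(is(model, "MetabolicModel"))
  direction <- match.arg(direction)
  lp <- .modelLP(model)
  j <- match(objective, lp$ids)
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  obj <- numeric(length(lp$ids)); obj[j] <- 1
  res <- .lpSolve(obj, lp$S, numeric(nrow(lp$S)), lp$lb, lp$ub,
                  maximize = direction == "max")
  if (res$status != "optimal")
    return(FluxDistribution(numeric(0), NA_real_, res$status))
  v <- stats::setNames(res$x, lp$ids)
  FluxDistribution(v, res$objval, "optimal")
}

#' Constrain growth to a fraction of its optimum
#'
#' Runs FBA on the biomass reaction and pins its bounds to
#' \code{[fraction * mu_opt, mu_opt]}, the standard preparation for
#' production-envelope questions ("maximum product rate at 95\% of optimal
#' growth").
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param fraction growth fraction in (0, 1]; default 0.95.
#' @return the growth-constrained model.
#' @examples
#' m <- fixGrowthFraction(makeRecombinantModel(), 0.95)
#' @export
fixGrowthFraction <- function(model, fraction = 0.95) {
  stopifnot(fraction > 0, fraction <= 1)
  sol <- fba(model)
  if (solverStatus(sol) != "optimal")
    stop("parent model has no optimal growth solution (status: ",
         solverStatus(sol), ")")
  mu <- objectiveValue(sol)
  bounds(model, objectiveReaction(model)) <- c(fraction * mu, mu)
  model
}

#' Robustness analysis
#'
#' Sweeps the allowed flux of one reaction over a grid and re-maximizes a
#' target reaction at each point, mapping the dependency of the target
#' optimum on the varied constraint (classically: product flux versus
#' oxygen uptake allowance).
#'
#' By default each grid value replaces the varied reaction's lower bound
#' (an uptake allowance); with \code{fixed = TRUE} the flux is pinned to
#' the grid value instead.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param target reaction whose optimum is recorded.
#' @param varied reaction whose bound is swept.
#' @param grid numeric vector of bound values.
#' @param fixed pin the varied flux (lb = ub = value) instead of setting
#'   only the lower bound.
#' @return data.frame \code{(bound, objective)} sorted by bound; an
#'   infeasible grid point is recorded as \code{NA}, not an error.
#' @examples
#' m <- makeNativeModel()
#' curve <- robustnessAnalysis(m, "EX_ha_e", "EX_o2_e", seq(0, -10, by = -2))
#' @export
robustnessAnalysis <- function(model, target, varied, grid, fixed = FALSE) {
  .rxnIndex(model, target); iv <- .rxnIndex(model, varied)
  ub0 <- model@reactions$ub[iv]
  out <- data.frame(bound = as.numeric(grid), objective = NA_real_)
  for (k in seq_along(grid)) {
    m2 <- model
    bnd <- if (fixed) c(grid[k], grid[k]) else c(grid[k], max(ub0, grid[k]))
    bounds(m2, varied) <- bnd
    sol <- fba(m2, objective = target)
    if (solverStatus(sol) == "optimal")
      out$objective[k] <- objectiveValue(sol)
  }
  out[order(out$bound), , drop = FALSE]
}

#' Metabolite flux from chemostat measurements
#'
#' Converts steady-state chemostat concentrations into a specific
#' exchange flux: \code{q = D * (C_supernatant - C_feed) / X_biomass}.
#' Uptake therefore comes out negative (supernatant below feed).
#'
#' @param D dilution rate (1/h), non-negative.
#' @param cSupernatant,cFeed metabolite concentration in the supernatant
#'   and the feed (mmol/L).
#' @param xBiomass biomass concentration (gDCW/L), strictly positive.
#' @return specific flux q in mmol/gDCW/h (vectorized).
#' @examples
#' chemostatFlux(0.3, 12, 2, 2)    #  1.5 (secretion)
#' chemostatFlux(0.4, 0, 20, 1)    # -8   (uptake)
#' @export
chemostatFlux <- function(D, cSupernatant, cFeed, xBiomass) {
  if (any(D < 0)) stop("dilution rate must be non-negative")
  if (any(xBiomass <= 0)) stop("biomass concentration must be positive")
  D * (cSupernatant - cFeed) / xBiomass
}

#' Rescale a flux distribution to a reference uptake rate
#'
#' Multiplies every flux by \code{targetUptake / |v_uptake|} so that flux
#' maps computed at different experimental uptake rates can be compared on
#' a common basis (conventionally 100 mmol glucose/gDCW/h). Steady state
#' is preserved by linearity.
#'
#' @param flux a \linkS4class{FluxDistribution} with optimal status.
#' @param uptakeReaction exchange reaction id whose flux anchors the
#'   scaling; its flux must be nonzero.
#' @param targetUptake target magnitude, default 100.
#' @return the rescaled \linkS4class{FluxDistribution}.
#' @examples
#' m <- makeNativeModel()
#' sol <- fba(m)
#' sol100 <- rescaleToUptake(sol, "EX_glc__D_e")
#' @export
rescaleToUptake <- function(flux, uptakeReaction, targetUptake = 100) {
  stopifnot(is(flux, "FluxDistribution"))
  if (solverStatus(flux) != "optimal")
    stop("cannot rescale a non-optimal flux distribution")
  v <- fluxes(flux)
  if (!uptakeReaction %in% names(v))
    stop("unknown reaction id: ", uptakeReaction)
  u <- v[[uptakeReaction]]
  if (abs(u) < .FEAS_TOL)
    stop("uptake flux through '", uptakeReaction, "' is zero; cannot rescale")
  f <- targetUptake / abs(u)
  FluxDistribution(v * f, objectiveValue(flux) * f, "optimal")
}

#' ATP yield per mole of glucose
#'
#' Measures pure catabolic ATP capacity: growth is fixed to zero, glucose
#' uptake to one unit, and the flux through the ATP maintenance
#' (hydrolysis) pseudo-reaction is maximized. The optimum is mol ATP per
#' mol glucose. Respiring networks with a full Krebs cycle and electron
#' transport chain score far above fermentative ones.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param glucoseExchange id of the glucose exchange reaction.
#' @param maintenanceReaction id of the ATP hydrolysis pseudo-reaction.
#' @return maximum ATP hydrolysis flux per unit glucose uptake (mol/mol).
#' @examples
#' atpYieldPerGlucose(makeNativeModel())       # fermentative
#' atpYieldPerGlucose(makeRecombinantModel())  # respiring, higher
#' @export
atpYieldPerGlucose <- function(model, glucoseExchange = "EX_glc__D_e",
                               maintenanceReaction = "ATPM") {
  .rxnIndex(model, maintenanceReaction)
  .rxnIndex(model, glucoseExchange)
  if (!is.na(objectiveReaction(model)))
    bounds(model, objectiveReaction(model)) <- c(0, 0)
  bounds(model, glucoseExchange) <- c(-1, -1)
  bounds(model, maintenanceReaction) <- c(0, 1000)
  sol <- fba(model, objective = maintenanceReaction)
  if (solverStatus(sol) != "optimal")
    stop("ATP yield LP not optimal (status: ", solverStatus(sol), ")")
  objectiveValue(sol)
}
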