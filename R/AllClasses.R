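#' MetabolicModel: a constraint-based metabolic model
#'
#' Container for a stoichiometric model: metabolites with elemental
#' formulas and charges, reactions with bounds and gene-protein-reaction
#' (GPR) rules, a gene list and an objective reaction. The convention for
#' exchange reactions is that uptake is negative flux and secretion
#' positive; reversible internal reactions carry bounds (-1000, 1000) and
#' irreversible ones (0, 1000), all in mmol/gDCW/h.
#'
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lb}, \code{ub}, \code{gpr} (infix boolean over gene ids, empty
#'   string for spontaneous/orphan reactions), \code{kind} (one of
#'   \code{"internal"}, \code{"exchange"}, \code{"transport"},
#'   \code{"pseudo"}) and \code{stoichiometry} (list column of named
#'   numeric vectors, metabolite id -> signed coefficient).
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula} (Hill-style elemental formula, empty if unknown),
#'   \code{charge} (integer) and \code{compartment}
#'   (\code{"intracellular"} or \code{"extracellular"}).
#' @slot genes character vector of gene ids; every GPR leaf must be here.
#' @slot objectiveReaction id of the objective (usually biomass) reaction.
#' @slot genomeGeneCount total gene count of the genome, used for model
#'   coverage statistics; \code{NA} if unknown.
#'
#' @seealso [makeNativeModel()], [makeRecombinantModel()], [readModel()],
#'   [fba()]
#' @export
setClass("MetabolicModel",
  representation(
    reactions = "data.frame",
    metabolites = "data.frame",
    genes = "character",
    objectiveReaction = "character",
    genomeGeneCount = "integer"
  ),
  prototype(
    reactions = data.frame(),
    metabolites = data.frame(),
    genes = character(0),
    objectiveReaction = NA_character_,
    genomeGeneCount = NA_integer_
  )
)

.RXN_KINDS <- c("internal", "exchange", "transport", "pseudo")
.COMPARTMENTS <- c("intracellular", "extracellular")

.validMetabolicModel <- function(object) {
  msgs <- character(0)
  rx <- object@reactions
  mets <- object@metabolites
  n_rxn <- nrow(rx)
  if (n_rxn > 0L) {
    need <- c("id", "name", "lb", "ub", "gpr", "kind", "stoichiometry")
    if (!all(need %in% names(rx)))
      return(paste("reactions lacks columns:",
                   paste(setdiff(need, names(rx)), collapse = ", ")))
    if (anyDuplicated(rx$id))
      msgs <- c(msgs, "duplicate reaction ids")
    if (any(rx$lb > rx$ub))
      msgs <- c(msgs, paste("lower bound exceeds upper bound for:",
                            paste(rx$id[rx$lb > rx$ub], collapse = ", ")))
    if (!all(rx$kind %in% .RXN_KINDS))
      msgs <- c(msgs, "unknown reaction kind")
    if (any(lengths(rx$stoichiometry) == 0L))
      msgs <- c(msgs, "reaction with empty stoichiometry")
  }
  if (nrow(mets) > 0L) {
    needm <- c("id", "name", "formula", "charge", "compartment")
    if (!all(needm %in% names(mets)))
      return(paste("metabolites lacks columns:",
                   paste(setdiff(needm, names(mets)), collapse = ", ")))
    if (anyDuplicated(mets$id))
      msgs <- c(msgs, "duplicate metabolite ids")
    if (!all(mets$compartment %in% .COMPARTMENTS))
      msgs <- c(msgs, "unknown compartment")
  }
  if (n_rxn > 0L) {
    used <- unique(unlist(lapply(rx$stoichiometry, names)))
    missing_mets <- setdiff(used, mets$id)
    if (length(missing_mets))
      msgs <- c(msgs, paste("stoichiometry references unknown metabolites:",
                            paste(missing_mets, collapse = ", ")))
    ## exchange reactions touch exactly one extracellular metabolite
    ext <- mets$id[mets$compartment == "extracellular"]
    for (i in which(rx$kind == "exchange")) {
      ids <- names(rx$stoichiometry[[i]])
      if (length(ids) != 1L || !(ids %in% ext)) {
        msgs <- c(msgs, paste0("exchange reaction '", rx$id[i],
          "' must touch exactly one extracellular metabolite"))
        break
      }
    }
    leaves <- unique(unlist(lapply(rx$gpr, gprGenes)))
    bad <- setdiff(leaves, object@genes)
    if (length(bad))
      msgs <- c(msgs, paste("GPR references unknown genes:",
                            paste(bad, collapse = ", ")))
    if (!is.na(object@objectiveReaction) &&
        !(object@objectiveReaction %in% rx$id))
      msgs <- c(msgs, "objective reaction not in model")
  }
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "duplicate gene ids")
  if (length(msgs)) msgs else TRUE
}

setValidity("MetabolicModel", .validMetabolicModel)

#' Construct a MetabolicModel
#'
#' @param reactions,metabolites data.frames as described in
#'   \linkS4class{MetabolicModel}.
#' @param genes character vector of gene ids.
#' @param objectiveReaction reaction id of the objective.
#' @param genomeGeneCount optional total genome gene count.
#' @return a validated \linkS4class{MetabolicModel}.
#' @export
MetabolicModel <- function(reactions, metabolites, genes = character(0),
                           objectiveReaction = NA_character_,
                           genomeGeneCount = NA_integer_) {
  new("MetabolicModel",
      reactions = reactions, metabolites = metabolites,
      genes = as.character(genes),
      objectiveReaction = as.character(objectiveReaction),
      genomeGeneCount = as.integer(genomeGeneCount))
}

#' FluxDistribution: one steady-state flux vector
#'
#' Result of an FBA or related optimization: one flux per reaction
#' (mmol/gDCW/h), the attained objective value, and the honest solver
#' status. When the status is "optimal" the vector satisfies S v = 0
#' within tolerance and all bounds.
#'
#' @slot fluxes named numeric vector, reaction id -> flux.
#' @slot objectiveValue attained objective (NA unless optimal).
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxDistribution",
  representation(
    fluxes = "numeric",
    objectiveValue = "numeric",
    status = "character"
  )
)

setValidity("FluxDistribution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  if (object@status == "optimal" && is.null(names(object@fluxes)))
    return("fluxes must be named by reaction id")
  TRUE
})

FluxDistribution <- function(fluxes, objectiveValue, status) {
  new("FluxDistribution", fluxes = fluxes,
      objectiveValue = as.numeric(objectiveValue), status = status)
}

#' MomaSolution: a MOMA projection of a reference flux state
#'
#' @slot solution the projected \linkS4class{FluxDistribution}, feasible
#'   in the perturbed model.
#' @slot distance squared Euclidean (quadratic mode) or L1 (linear mode)
#'   distance to the reference; NA when infeasible.
#' @slot referenceId provenance string for the reference state.
#' @slot mode "quadratic" or "linear".
#' @export
setClass("MomaSolution",
  representation(
    solution = "FluxDistribution",
    distance = "numeric",
    referenceId = "character",
    mode = "character"
  )
)

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object) object@metabolites)

#' @rdname accessors
#' @export
setMethod("genes", "MetabolicModel", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel",
          function(object) object@objectiveReaction)

#' @rdname accessors
#' @export
setReplaceMethod("objectiveReaction", "MetabolicModel",
  function(object, value) {
    object@objectiveReaction <- as.character(value)
    validObject(object)
    object
  })

#' @rdname accessors
#' @export
setMethod("bounds", "MetabolicModel", function(object) {
  data.frame(reaction = object@reactions$id,
             lb = object@reactions$lb, ub = object@reactions$ub)
})

#' @rdname accessors
#' @export
setReplaceMethod("bounds", "MetabolicModel",
  function(object, reaction, value) {
    idx <- match(reaction, object@reactions$id)
    if (anyNA(idx))
      stop("unknown reaction id: ",
           paste(reaction[is.na(idx)], collapse = ", "))
    value <- matrix(as.numeric(value), ncol = 2)
    object@reactions$lb[idx] <- value[, 1]
    object@reactions$ub[idx] <- value[, 2]
    validObject(object)
    object
  })

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxDistribution", function(object) object@fluxes)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxDistribution",
          function(object) object@objectiveValue)

#' @rdname accessors
#' @export
setMethod("solverStatus", "FluxDistribution", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("fluxes", "MomaSolution",
          function(object) object@solution@fluxes)

#' @rdname accessors
#' @export
setMethod("solverStatus", "MomaSolution",
          function(object) object@solution@status)

#' Distance of a MOMA solution to its reference
#' @param x a \linkS4class{MomaSolution}.
#' @return squared Euclidean (quadratic mode) or L1 distance.
#' @export
momaDistance <- function(x) {
  stopifnot(is(x, "MomaSolution"))
  x@distance
}

## ---- show methods --------------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
  rx <- object@reactions
  cat("MetabolicModel with", nrow(rx), "reactions,",
      nrow(object@metabolites), "metabolites,",
      length(object@genes), "genes\n")
  if (nrow(rx)) {
    tab <- table(factor(rx$kind, levels = .RXN_KINDS))
    cat("  reactions by kind:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  objective:", object@objectiveReaction, "\n")
  if (!is.na(object@genomeGeneCount))
    cat("  genome genes:", object@genomeGeneCount, "\n")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, ")\n", sep = "")
  if (object@status == "optimal") {
    cat("  objective value:", format(object@objectiveValue, digits = 6), "\n")
    nz <- sum(abs(object@fluxes) > 1e-6)
    cat("  ", nz, " of ", length(object@fluxes),
        " reactions carry |flux| > 1e-6\n", sep = "")
  }
})

setMethod("show", "MomaSolution", function(object) {
  cat("MomaSolution (", object@solution@status, ", mode=", object@mode,
      ")\n", sep = "")
  if (object@solution@status == "optimal")
    cat("  distance to reference '", object@referenceId, "': ",
        format(object@distance, digits = 6), "\n", sep = "")
})
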