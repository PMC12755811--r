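#' @import methods
NULL

#' Accessors for metabolic models and flux distributions
#'
#' @param object a \linkS4class{MetabolicModel},
#'   \linkS4class{FluxDistribution} or \linkS4class{MomaSolution}.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction",
           function(object) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction<-",
           function(object, value) standardGeneric("objectiveReaction<-"))

#' @rdname accessors
#' @export
setGeneric("bounds", function(object) standardGeneric("bounds"))

#' @rdname accessors
#' @param reaction reaction id(s) whose bounds are replaced.
#' @export
setGeneric("bounds<-",
           function(object, reaction, value) standardGeneric("bounds<-"))

#' Stoichiometric matrix of a model
#'
#' Materializes the metabolites-by-reactions coefficient matrix S used by
#' all solvers; entry (i, j) is the signed coefficient of metabolite i in
#' reaction j.
#'
#' @param object a \linkS4class{MetabolicModel}.
#' @param sparse logical; return a sparse \code{Matrix} (default) or a
#'   dense base matrix.
#' @return a \code{dgCMatrix} (or dense matrix) with metabolite ids as row
#'   names and reaction ids as column names; 0 x 0 for an empty model.
#' @examples
#' m <- makeNativeModel()
#' dim(stoichiometricMatrix(m))
#' @export
setGeneric("stoichiometricMatrix",
           function(object, sparse = TRUE) standardGeneric("stoichiometricMatrix"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue",
           function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' Delete genes from a model
#'
#' Applies gene-protein-reaction (GPR) logic: every reaction whose GPR rule
#' evaluates to FALSE once the given genes are removed has its bounds set
#' to (0, 0); reactions with an empty GPR, or whose rule is still
#' satisfiable through isozymes, are untouched.
#'
#' @param object a \linkS4class{MetabolicModel}.
#' @param geneSet character vector of gene ids to remove (all must be in
#'   \code{genes(object)}).
#' @return the knocked-out \linkS4class{MetabolicModel}.
#' @examples
#' m <- makeNativeModel()
#' ko <- knockout(m, "ldh_syn")
#' @export
setGeneric("knockout", function(object, geneSet) standardGeneric("knockout"))
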