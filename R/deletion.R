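## Gene deletion screens and interaction classification.
##
## Knockouts act through GPR logic; growth phenotypes are summarized as
## the relative growth rate Rgr = mutant growth / wild-type growth.
## Numerical guards: a mutant is lethal when Rgr < 1e-6 (the LP noise
## floor) and sick when Rgr < 1 - 1e-3; a pair interacts when its double
## Rgr falls below both single Rgrs by more than 1e-6.

.LETHAL_TOL <- 1e-6
.SICK_TOL <- 1e-3

#' @rdname knockout
#' @export
setMethod("knockout", "MetabolicModel", function(object, geneSet) {
  geneSet <- as.character(geneSet)
  unknown <- setdiff(geneSet, object@genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  present <- setdiff(object@genes, geneSet)
  rx <- object@reactions
  for (i in seq_len(nrow(rx))) {
    if (!nzchar(rx$gpr[i])) next
    if (!gprEval(rx$gpr[i], present)) {
      rx$lb[i] <- 0
      rx$ub[i] <- 0
    }
  }
  object@reactions <- rx
  object
})

## growth of a knockout strain under the requested method
.mutantGrowth <- function(model, geneSet, method, reference) {
  km <- knockout(model, geneSet)
  if (method == "fba") {
    sol <- fba(km)
    if (solverStatus(sol) != "optimal") return(0)
    max(objectiveValue(sol), 0)
  } else {
    sol <- moma(km, reference)
    if (solverStatus(sol) != "optimal") return(0)
    max(fluxes(sol)[[objectiveReaction(model)]], 0)
  }
}

.classifySingle <- function(rgr) {
  ifelse(rgr < .LETHAL_TOL, "lethal",
         ifelse(rgr < 1 - .SICK_TOL, "sick", "neutral"))
}

#' Single-gene deletion screen
#'
#' Deletes each gene in turn and reports the relative growth rate
#' Rgr = mutant growth / wild-type growth, with classes \code{lethal}
#' (Rgr below the zero tolerance), \code{sick} (Rgr meaningfully below 1)
#' and \code{neutral}. Growth comes from FBA (re-optimized mutant) or
#' MOMA (projection of the wild-type reference) per \code{method}.
#'
#' @param model a \linkS4class{MetabolicModel}; wild-type growth must be
#'   positive.
#' @param method \code{"fba"} (default) or \code{"moma"}.
#' @param geneSet genes to screen; default all model genes.
#' @return data.frame \code{(gene, growth, Rgr, method, class)}.
#' @examples
#' m <- makeNativeModel()
#' screen <- singleGeneDeletion(m)
#' table(screen$class)
#' @export
singleGeneDeletion <- function(model, method = c("fba", "moma"),
                               geneSet = genes(model)) {
  method <- match.arg(method)
  wt <- fba(model)
  if (solverStatus(wt) != "optimal" || objectiveValue(wt) <= .LETHAL_TOL)
    stop("wild-type model does not grow; screen is undefined")
  mu <- objectiveValue(wt)
  reference <- if (method == "moma") referenceState(model) else NULL
  growth <- vapply(geneSet, function(g)
    .mutantGrowth(model, g, method, reference), 0)
  rgr <- growth / mu
  data.frame(gene = geneSet, growth = unname(growth), Rgr = unname(rgr),
             method = method, class = .classifySingle(unname(rgr)),
             row.names = NULL)
}

#' Double-gene deletion screen
#'
#' Screens all unordered gene pairs. Two genes interact when the double
#' mutant grows strictly worse than either single mutant; an interacting
#' pair is \code{synthetic_lethal} when the double Rgr is zero although
#' both singles grow, and \code{synthetic_sick} when the double Rgr is
#' below both singles (and below 1) but still positive. Pairs containing
#' a lethal single are skipped arithmetically (their double Rgr is 0 with
#' no new information) and classified \code{no_interaction}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param method \code{"fba"} (default, as in genome-wide interaction
#'   screens) or \code{"moma"}.
#' @param singles optional precomputed [singleGeneDeletion()] result with
#'   the same method; computed if missing.
#' @param geneSet genes to screen; default all model genes.
#' @return data.frame \code{(gene1, gene2, Rgr, method, class)}.
#' @examples
#' m <- makeNativeModel()
#' doubles <- doubleGeneDeletion(m)
#' subset(doubles, class != "no_interaction")
#' @export
doubleGeneDeletion <- function(model, method = c("fba", "moma"),
                               singles = NULL, geneSet = genes(model)) {
  method <- match.arg(method)
  if (is.null(singles))
    singles <- singleGeneDeletion(model, method, geneSet = geneSet)
  stopifnot(all(geneSet %in% singles$gene))
  wt <- fba(model)
  mu <- objectiveValue(wt)
  reference <- if (method == "moma") referenceState(model) else NULL
  srgr <- stats::setNames(singles$Rgr, singles$gene)
  ng <- length(geneSet)
  if (ng < 2L)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      Rgr = numeric(0), method = character(0),
                      class = character(0)))
  pairs <- utils::combn(geneSet, 2L)
  n_pairs <- ncol(pairs)
  rgr <- numeric(n_pairs)
  cls <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    s1 <- srgr[[g1]]; s2 <- srgr[[g2]]
    if (min(s1, s2) < .LETHAL_TOL) {
      ## double of a lethal single is lethal but not an interaction
      rgr[k] <- 0
      cls[k] <- "no_interaction"
      next
    }
    r <- .mutantGrowth(model, c(g1, g2), method, reference) / mu
    rgr[k] <- r
    interacting <- r < min(s1, s2) - .LETHAL_TOL
    cls[k] <- if (!interacting) "no_interaction"
      else if (r < .LETHAL_TOL) "synthetic_lethal"
      else if (r < 1 - .SICK_TOL) "synthetic_sick"
      else "no_interaction"
  }
  data.frame(gene1 = pairs[1, ], gene2 = pairs[2, ], Rgr = rgr,
             method = method, class = cls, row.names = NULL)
}

#' Summarize deletion screens as gene percentages
#'
#' Collapses single and double screens into the percentages used to
#' compare network robustness between organisms: lethal and sick single
#' deletions, and synthetic-lethal / synthetic-sick genes by interaction
#' degree. A gene's degree is its number of partners in the given
#' interaction class; the "1 interaction" columns count genes with exactly
#' one partner and the ">=5" columns genes with five or more. All
#' percentages use the total model gene count as denominator.
#'
#' @param singles result of [singleGeneDeletion()].
#' @param doubles result of [doubleGeneDeletion()].
#' @param nGenes total gene count (denominator); default the number of
#'   genes in \code{singles}.
#' @return named list with components \code{pct_lethal}, \code{pct_sick},
#'   \code{pct_synthetic_lethal_1}, \code{pct_synthetic_sick_1},
#'   \code{pct_synthetic_lethal_ge5}, \code{pct_synthetic_sick_ge5}.
#' @export
summarizeInteractions <- function(singles, doubles,
                                  nGenes = nrow(singles)) {
  stopifnot(nGenes > 0)
  degree <- function(class) {
    sel <- doubles$class == class
    tab <- table(c(doubles$gene1[sel], doubles$gene2[sel]))
    as.vector(tab)
  }
  pct <- function(x) 100 * x / nGenes
  dl <- degree("synthetic_lethal")
  ds <- degree("synthetic_sick")
  list(
    pct_lethal = pct(sum(singles$class == "lethal")),
    pct_sick = pct(sum(singles$class == "sick")),
    pct_synthetic_lethal_1 = pct(sum(dl == 1L)),
    pct_synthetic_sick_1 = pct(sum(ds == 1L)),
    pct_synthetic_lethal_ge5 = pct(sum(dl >= 5L)),
    pct_synthetic_sick_ge5 = pct(sum(ds >= 5L))
  )
}
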