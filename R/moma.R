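## Minimization of metabolic adjustment (MOMA).
##
## A knockout strain has had no time to re-regulate toward a new optimum,
## so its flux state is predicted as the feasible point of the perturbed
## model closest to the wild-type reference -- squared Euclidean distance
## by default (a strictly convex QP with a unique solution), L1 optionally.

#' Deterministic wild-type reference state
#'
#' Computes the reference flux vector MOMA projects from: an FBA optimum
#' for biomass, disambiguated among alternate optima by minimizing total
#' absolute flux (sum |v|) at fixed optimal growth. The secondary
#' objective makes the reference seedless and reproducible, which in turn
#' makes every downstream mutant prediction reproducible.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return a \linkS4class{FluxDistribution} whose objective value equals
#'   the plain FBA growth optimum.
#' @examples
#' ref <- referenceState(makeNativeModel())
#' objectiveValue(ref)
#' @export
referenceState <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  sol <- fba(model)
  if (solverStatus(sol) != "optimal")
    stop("model is not feasible (status: ", solverStatus(sol), ")")
  mu <- objectiveValue(sol)
  lp <- .modelLP(model)
  n <- length(lp$ids)
  jb <- match(objectiveReaction(model), lp$ids)
  lb <- lp$lb; ub <- lp$ub
  lb[jb] <- mu; ub[jb] <- mu
  ## v = p - q with p, q >= 0; min sum(p + q) realizes min sum |v|
  pl <- pmax(lb, 0); pu <- pmax(ub, 0)
  ql <- pmax(-ub, 0); qu <- pmax(-lb, 0)
  A <- cbind(lp$S, -lp$S)
  res <- .lpSolve(rep(1, 2 * n), A, numeric(nrow(lp$S)),
                  c(pl, ql), c(pu, qu), maximize = FALSE)
  if (res$status != "optimal")
    stop("minimal-flux reference LP failed (status: ", res$status, ")")
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)], lp$ids)
  FluxDistribution(v, mu, "optimal")
}

#' Minimization of metabolic adjustment
#'
#' Projects a wild-type reference flux state onto the feasible space of a
#' perturbed (knockout) model: minimizes \code{sum((v - v_ref)^2)}
#' (quadratic mode, unique solution) or \code{sum(|v - v_ref|)} (linear
#' mode) subject to S v = 0 and the perturbed bounds. The mutant growth
#' and product rates are read off the projection.
#'
#' @param model the perturbed \linkS4class{MetabolicModel}.
#' @param reference a \linkS4class{FluxDistribution}, usually
#'   [referenceState()] of the unperturbed model. Reactions of the model
#'   absent from the reference are treated as reference flux 0.
#' @param mode \code{"quadratic"} (default) or \code{"linear"}.
#' @param referenceId provenance string stored in the result.
#' @return a \linkS4class{MomaSolution}; on an infeasible perturbed model
#'   the embedded status is \code{"infeasible"} and the distance NA.
#' @examples
#' m <- makeNativeModel()
#' ref <- referenceState(m)
#' sol <- moma(knockout(m, "asd_syn"), ref)
#' fluxes(sol)[["BIOMASS"]]   # mutant growth prediction
#' momaDistance(sol)
#' @export
moma <- function(model, reference, mode = c("quadratic", "linear"),
                 referenceId = "wild-type") {
  stopifnot(is(model, "MetabolicModel"), is(reference, "FluxDistribution"))
  mode <- match.arg(mode)
  lp <- .modelLP(model)
  n <- length(lp$ids)
  ref <- stats::setNames(numeric(n), lp$ids)
  hit <- intersect(lp$ids, names(fluxes(reference)))
  ref[hit] <- fluxes(reference)[hit]

  if (mode == "quadratic") {
    ## min 1/2 v' (2I) v - (2 ref)' v  s.t.  S v = 0, lb <= v <= ub.
    ## Fixed variables (lb == ub, e.g. knocked-out reactions) are
    ## eliminated before calling the solver: expressed as opposing
    ## inequalities they are exactly degenerate and break
    ## Goldfarb-Idnani. Conserved moieties make S row-deficient, so only
    ## a row basis of the reduced system is passed as equalities (the
    ## dropped dependent rows are implied whenever the model is
    ## feasible, which FBA feasibility guarantees).
    lbq <- pmax(lp$lb, -1e7); ubq <- pmin(lp$ub, 1e7)  # quadprog needs finite
    ## any feasible point serves as the particular solution; a
    ## zero-objective LP is a cheap feasibility check
    feas <- .lpSolve(numeric(n), lp$S, numeric(nrow(lp$S)), lp$lb, lp$ub)
    if (feas$status != "optimal") {
      fd <- FluxDistribution(numeric(0), NA_real_, feas$status)
      return(new("MomaSolution", solution = fd, distance = NA_real_,
                 referenceId = referenceId, mode = mode))
    }
    v0 <- feas$x                            # particular steady-state point
    ## fixed variables (knocked-out reactions, pinned exchanges) join the
    ## equality system: expressed as opposing box inequalities they are
    ## exactly degenerate and break the QP solver
    fixed <- lbq == ubq
    Saug <- rbind(lp$S, diag(n)[fixed, , drop = FALSE])
    qrS <- qr(t(Saug))
    rk <- qrS$rank
    if (rk >= n) {
      v <- v0                               # steady state is a single point
    } else {
      ## v = v0 + N z with N an orthonormal null-space basis: the QP in z
      ## has only box constraints and stays well conditioned
      N <- qr.Q(qrS, complete = TRUE)[, (rk + 1):n, drop = FALSE]
      Nb <- N[!fixed, , drop = FALSE]
      Dmat <- 2 * crossprod(N)
      dvec <- 2 * as.vector(crossprod(N, ref - v0))
      Amat <- cbind(t(Nb), -t(Nb))
      ## 1e-9 slack guards against exactly-degenerate active sets (v0 is
      ## an LP vertex, so many box constraints are tight to machine
      ## precision); the solution is clipped back into the box below
      bvec <- c((lbq - v0)[!fixed], (v0 - ubq)[!fixed]) - 1e-9
      fit <- tryCatch(
        quadprog::solve.QP(Dmat = Dmat, dvec = dvec, Amat = Amat,
                           bvec = bvec),
        error = function(e) NULL)
      if (is.null(fit)) {
        fd <- FluxDistribution(numeric(0), NA_real_, "infeasible")
        return(new("MomaSolution", solution = fd, distance = NA_real_,
                   referenceId = referenceId, mode = mode))
      }
      v <- v0 + as.vector(N %*% fit$solution)
    }
    v <- stats::setNames(pmin(pmax(v, lbq), ubq), lp$ids)
    dist <- sum((v - ref)^2)
  } else {
    ## v = ref + p - q, p,q >= 0; min sum(p + q); the lower bounds force
    ## v back inside the box when the reference is infeasible there
    pl <- pmax(lp$lb - ref, 0); pu <- pmax(lp$ub - ref, 0)
    ql <- pmax(ref - lp$ub, 0); qu <- pmax(ref - lp$lb, 0)
    A <- cbind(lp$S, -lp$S)
    rhs <- as.vector(-lp$S %*% ref)
    res <- .lpSolve(rep(1, 2 * n), A, rhs, c(pl, ql), c(pu, qu),
                    maximize = FALSE)
    if (res$status != "optimal") {
      fd <- FluxDistribution(numeric(0), NA_real_, res$status)
      return(new("MomaSolution", solution = fd, distance = NA_real_,
                 referenceId = referenceId, mode = mode))
    }
    v <- stats::setNames(ref + res$x[seq_len(n)] - res$x[n + seq_len(n)],
                         lp$ids)
    dist <- sum(abs(v - ref))
  }
  jb <- match(objectiveReaction(model), lp$ids)
  obj <- if (is.na(jb)) NA_real_ else v[[jb]]
  fd <- FluxDistribution(v, obj, "optimal")
  new("MomaSolution", solution = fd, distance = dist,
      referenceId = referenceId, mode = mode)
}
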