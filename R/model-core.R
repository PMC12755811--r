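## Core model operations: matrix materialization, elemental/charge balance
## checking and medium application.

#' @rdname stoichiometricMatrix
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
  function(object, sparse = TRUE) {
    rx <- object@reactions
    mets <- object@metabolites$id
    if (nrow(rx) == 0L || length(mets) == 0L) {
      S <- Matrix::Matrix(0, 0, 0, sparse = TRUE)
      return(if (sparse) S else as.matrix(S))
    }
    if (anyDuplicated(rx$id) || anyDuplicated(mets))
      stop("duplicate reaction or metabolite ids")
    ii <- jj <- integer(0); xx <- numeric(0)
    for (j in seq_len(nrow(rx))) {
      st <- rx$stoichiometry[[j]]
      idx <- match(names(st), mets)
      if (anyNA(idx))
        stop("reaction '", rx$id[j], "' references unknown metabolites")
      ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(st)))
      xx <- c(xx, unname(st))
    }
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(length(mets), nrow(rx)),
                              dimnames = list(mets, rx$id))
    if (sparse) S else as.matrix(S)
  })

## ---- elemental formulas --------------------------------------------------

## Hill-style formula -> named element counts ("C6H11O9P" -> c(C=6,H=11,...))
.parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  parts <- regmatches(formula,
                      gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(sub("^[A-Za-z]+", "", parts))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, Mg = 24.305, Fe = 55.845,
                  K = 39.098, Na = 22.99, Cl = 35.45)

## molecular weight in g/mol from a formula string
.formulaWeight <- function(formula) {
  counts <- .parseFormula(formula)
  if (is.null(counts)) return(NA_real_)
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(counts * .ATOMIC_MASS[names(counts)])
}

## ---- balance checking ----------------------------------------------------

#' Check elemental and charge balance of reactions
#'
#' Tallies atoms and charge on both sides of each reaction. Exchange and
#' pseudo reactions (biomass, maintenance, polymer condensation drains)
#' are flagged exempt rather than unbalanced; reactions touching a
#' metabolite without a formula are flagged unbalanceable rather than
#' failing.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param reaction optional character vector of reaction ids; default all.
#' @return data.frame with one row per reaction: \code{reaction},
#'   \code{kind}, \code{status} (\code{"balanced"}, \code{"unbalanced"},
#'   \code{"exempt"}, \code{"unbalanceable"}), \code{max_residual} (largest
#'   absolute per-element residual), \code{charge_residual}, and a list
#'   column \code{residuals} of per-element residuals (products minus
#'   substrates, weighted by coefficients).
#' @examples
#' m <- makeNativeModel()
#' tab <- checkBalance(m)
#' table(tab$status)
#' @export
checkBalance <- function(model, reaction = NULL) {
  stopifnot(is(model, "MetabolicModel"))
  rx <- model@reactions
  if (!is.null(reaction)) {
    idx <- match(reaction, rx$id)
    if (anyNA(idx))
      stop("unknown reaction id: ",
           paste(reaction[is.na(idx)], collapse = ", "))
    rx <- rx[idx, , drop = FALSE]
  }
  mets <- model@metabolites
  met_formula <- stats::setNames(mets$formula, mets$id)
  met_charge <- stats::setNames(mets$charge, mets$id)
  tol <- 1e-6
  out <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[i]]
    if (rx$kind[i] %in% c("exchange", "pseudo")) {
      out[[i]] <- list(status = "exempt", max_residual = NA_real_,
                       charge_residual = NA_real_, residuals = numeric(0))
      next
    }
    fs <- met_formula[names(st)]
    if (any(is.na(fs) | !nzchar(fs))) {
      out[[i]] <- list(status = "unbalanceable", max_residual = NA_real_,
                       charge_residual = NA_real_, residuals = numeric(0))
      next
    }
    resid <- numeric(0)
    for (k in seq_along(st)) {
      counts <- .parseFormula(fs[k])
      for (el in names(counts)) {
        resid[el] <- (if (el %in% names(resid)) resid[el] else 0) +
          st[k] * counts[[el]]
      }
    }
    resid <- resid[order(names(resid))]
    chg <- sum(st * met_charge[names(st)])
    status <- if (all(abs(resid) <= tol) && abs(chg) <= tol)
      "balanced" else "unbalanced"
    out[[i]] <- list(status = status,
                     max_residual = if (length(resid)) max(abs(resid)) else 0,
                     charge_residual = chg, residuals = resid)
  }
  data.frame(
    reaction = rx$id,
    kind = rx$kind,
    status = vapply(out, `[[`, "", "status"),
    max_residual = vapply(out, `[[`, 0, "max_residual"),
    charge_residual = vapply(out, `[[`, 0, "charge_residual"),
    residuals = I(lapply(out, `[[`, "residuals"))
  )
}

## ---- media ---------------------------------------------------------------

#' Define a growth medium as exchange-reaction bounds
#'
#' @param reaction character vector of exchange reaction ids.
#' @param lb,ub numeric bounds (uptake negative, secretion positive).
#' @return a \code{data.frame} of class \code{"hyaflux_medium"}.
#' @examples
#' med <- medium(c("EX_glc", "EX_o2"), lb = c(-18.56, 0), ub = c(1000, 1000))
#' @export
medium <- function(reaction, lb, ub = 1000) {
  d <- data.frame(reaction = as.character(reaction),
                  lb = as.numeric(lb),
                  ub = rep_len(as.numeric(ub), length(reaction)))
  if (any(d$lb > d$ub)) stop("medium has lb > ub")
  class(d) <- c("hyaflux_medium", class(d))
  d
}

#' Apply a medium to a model
#'
#' Overwrites the bounds of the exchange reactions listed in the medium
#' and closes uptake (lower bound 0) for every exchange reaction not
#' listed; secretion bounds of unlisted exchanges and all
#' internal/transport/pseudo bounds are untouched.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a [medium()] table (reaction, lb, ub).
#' @return the constrained model.
#' @examples
#' m <- makeNativeModel()
#' anaerobic <- applyMedium(m, medium("EX_glc__D_e", lb = -18.56))
#' @export
applyMedium <- function(model, medium) {
  stopifnot(is(model, "MetabolicModel"), is.data.frame(medium))
  rx <- model@reactions
  idx <- match(medium$reaction, rx$id)
  if (anyNA(idx))
    stop("medium references unknown reaction(s): ",
         paste(medium$reaction[is.na(idx)], collapse = ", "))
  if (any(rx$kind[idx] != "exchange"))
    stop("medium may only reference exchange reactions: ",
         paste(medium$reaction[rx$kind[idx] != "exchange"], collapse = ", "))
  ## close uptake of all unlisted exchanges, keep their secretion bounds
  unlisted <- setdiff(which(rx$kind == "exchange"), idx)
  rx$lb[unlisted] <- pmax(rx$lb[unlisted], 0)
  rx$lb[idx] <- medium$lb
  rx$ub[idx] <- medium$ub
  model@reactions <- rx
  validObject(model)
  model
}

## internal: index of a reaction id, with a clear error
.rxnIndex <- function(model, id) {
  i <- match(id, model@reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  i
}
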