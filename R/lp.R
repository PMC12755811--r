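## Bounded-variable primal simplex.
##
## FBA needs a linear-programming kernel that is exact at optima and
## bit-reproducible across runs.  This is a dense two-phase simplex for
##   max/min  c'x   s.t.  A x (=, <=, >=) b,   lb <= x <= ub
## with box bounds handled natively (no variable splitting).  Nonbasic
## variables may rest at an interior value (superbasic), which lets every
## run start from x ~ 0: steady-state rows are then satisfied at the
## start and phase 1 is near-instant.
##
## Pivoting is Dantzig's rule with deterministic smallest-index
## tie-breaks, falling back to Bland's rule after a run of degenerate
## steps so cycling is impossible.  Every variable must carry at least
## one finite bound (metabolic fluxes always do; slacks are bounded on
## one side).

.LP_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' Internal simplex used by [fba()] and friends. Maximizes (or minimizes)
#' \code{obj'x} subject to \code{A x (sense) b} and \code{lb <= x <= ub}.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or sparse.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n); every variable needs at least
#'   one finite bound.
#' @param maximize logical; maximize (default) or minimize.
#' @param sense character vector of row senses, each \code{"="},
#'   \code{"<="} or \code{">="}; recycled if length 1.
#' @return list with \code{status} ("optimal", "infeasible" or
#'   "unbounded"), \code{x} (solution, length n) and \code{objval}.
#' @keywords internal
#' @noRd
.lpSolve <- function(obj, A, b, lb, ub, maximize = TRUE, sense = "=") {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + .LP_TOL))
    stop("lower bound exceeds upper bound in LP")
  sense <- rep_len(sense, m)

  ## slacks turn inequality rows into equalities
  n_slack <- sum(sense != "=")
  if (n_slack > 0L) {
    Sl <- matrix(0, m, n_slack)
    k <- 0L
    slb <- sub <- numeric(n_slack)
    for (i in seq_len(m)) {
      if (sense[i] == "=") next
      k <- k + 1L
      Sl[i, k] <- 1
      if (sense[i] == "<=") { slb[k] <- 0;    sub[k] <- Inf }
      else                  { slb[k] <- -Inf; sub[k] <- 0 }
    }
    A  <- cbind(A, Sl)
    obj <- c(obj, numeric(n_slack))
    lb <- c(lb, slb); ub <- c(ub, sub)
  }
  if (any(!is.finite(lb) & !is.finite(ub)))
    stop("LP variables must have at least one finite bound")

  if (!maximize) obj <- -obj
  res <- .simplexCore(obj, A, b, lb, ub)
  if (res$status == "optimal") {
    res$x <- res$x[seq_len(n)]
    res$objval <- if (maximize) res$objval else -res$objval
  } else {
    res$x <- rep(NA_real_, n)
    res$objval <- NA_real_
  }
  res
}

## core: maximize c'x s.t. A x = b, lb <= x <= ub (all equalities)
.simplexCore <- function(cc, A, b, lb, ub) {
  m <- nrow(A); n <- ncol(A)
  if (n == 0L) {
    ok <- m == 0L || max(abs(b)) <= 1e-7
    return(list(status = if (ok) "optimal" else "infeasible",
                x = numeric(0), objval = 0))
  }
  ## start each variable as close to zero as its box allows
  x <- pmin(pmax(0, lb), ub)
  if (m == 0L) {
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, x))
    if (any(!is.finite(x[cc != 0])))
      return(list(status = "unbounded", x = NULL, objval = NA_real_))
    return(list(status = "optimal", x = x, objval = sum(cc * x)))
  }
  ## nonbasic position: -1 at lower bound, +1 at upper, 0 interior
  pos <- integer(n)
  pos[x == lb] <- -1L
  pos[x == ub & lb < ub] <- 1L

  ## artificials, one per row, signed to absorb the start residual
  r <- as.vector(b - A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lbf <- c(lb, numeric(m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x, abs(r))
  pos <- c(pos, rep(-1L, m))
  basis <- n + seq_len(m)
  art <- n + seq_len(m)

  phase1 <- c(numeric(n), rep(-1, m))    # maximize -(sum of artificials)
  st <- .simplexIterate(phase1, Afull, lbf, ubf, xf, pos, basis)
  if (st$status != "optimal" || sum(st$x[art]) > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NA_real_))

  ## pin artificials at zero and optimize the true objective
  lbf[art] <- 0; ubf[art] <- 0
  st <- .simplexIterate(c(cc, numeric(m)), Afull, lbf, ubf,
                        st$x, st$pos, st$basis)
  if (st$status != "optimal")
    return(list(status = st$status, x = NULL, objval = NA_real_))

  ## tighten basic values against accumulated drift
  xb <- st$x
  inb <- logical(n + m); inb[st$basis] <- TRUE
  rhs <- b - Afull[, !inb, drop = FALSE] %*% xb[!inb]
  sol <- try(solve(Afull[, st$basis, drop = FALSE], rhs), silent = TRUE)
  if (!inherits(sol, "try-error")) xb[st$basis] <- as.vector(sol)
  x <- xb[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(cc * x))
}

## simplex main loop (maximization, equality form with box bounds);
## nonbasic variables may rest at interior values (pos == 0). The basis
## inverse is maintained by product-form rank-1 updates and refactorized
## periodically for numerical hygiene.
.simplexIterate <- function(cc, A, lb, ub, x, pos, basis,
                            max_iter = 20000L) {
  m <- nrow(A); nt <- ncol(A)
  inb <- logical(nt); inb[basis] <- TRUE
  degen <- 0L
  refactor <- function() {
    Bi <- try(solve(A[, basis, drop = FALSE]), silent = TRUE)
    if (inherits(Bi, "try-error"))
      Bi <- qr.solve(A[, basis, drop = FALSE] + diag(1e-12, m))
    Bi
  }
  Binv <- refactor()
  since_refactor <- 0L
  fixedv <- lb == ub
  for (iter in seq_len(max_iter)) {
    if (since_refactor >= 60L) {
      Binv <- refactor()
      since_refactor <- 0L
    }
    y <- as.vector(crossprod(Binv, cc[basis]))
    d <- cc - as.vector(crossprod(A, y))
    improving <- !inb & !fixedv &
      ((pos == -1L & d > .LP_TOL) |
       (pos ==  1L & d < -.LP_TOL) |
       (pos ==  0L & abs(d) > .LP_TOL))
    if (!any(improving))
      return(list(status = "optimal", x = x, pos = pos, basis = basis))
    if (degen >= 30L) {
      j <- which.max(improving)                    # Bland: smallest index
    } else {
      dmask <- abs(d) * improving
      j <- which.max(dmask)                        # Dantzig, first max
    }
    dj <- d[j]
    tdir <- if (pos[j] == -1L) 1 else if (pos[j] == 1L) -1 else sign(dj)
    w <- as.vector(Binv %*% A[, j])
    step_basic <- tdir * w
    ## ratio test against basic variable bounds
    lims <- rep(Inf, m)
    bx <- x[basis]
    up <- step_basic > .LP_TOL
    dn <- step_basic < -.LP_TOL
    if (any(up))
      lims[up] <- pmax((bx[up] - lb[basis[up]]) / step_basic[up], 0)
    if (any(dn))
      lims[dn] <- pmax((ub[basis[dn]] - bx[dn]) / (-step_basic[dn]), 0)
    flip <- if (tdir > 0) ub[j] - x[j] else x[j] - lb[j]
    theta_basic <- min(lims)
    theta <- min(flip, theta_basic)
    if (!is.finite(theta))
      return(list(status = "unbounded", x = x, pos = pos, basis = basis))
    leave <- 0L
    if (theta_basic <= theta + .LP_TOL) {
      ties <- which(lims <= theta + .LP_TOL)
      leave <- ties[which.min(basis[ties])]        # Bland-style tie-break
      theta <- lims[leave]
    }
    degen <- if (theta <= .LP_TOL) degen + 1L else 0L
    ## update values
    x[j] <- x[j] + tdir * theta
    x[basis] <- x[basis] - theta * step_basic
    if (leave == 0L) {
      pos[j] <- if (tdir > 0) 1L else -1L          # bound flip
    } else {
      bl <- basis[leave]
      hit_lower <- step_basic[leave] > 0
      x[bl] <- if (hit_lower) lb[bl] else ub[bl]
      pos[bl] <- if (hit_lower) -1L else 1L
      inb[bl] <- FALSE
      basis[leave] <- j
      inb[j] <- TRUE
      pos[j] <- 0L
      ## product-form update of the basis inverse
      if (abs(w[leave]) < 1e-8) {
        Binv <- refactor()
        since_refactor <- 0L
      } else {
        brow <- Binv[leave, ]
        Binv <- Binv - outer(w, brow) / w[leave]
        Binv[leave, ] <- brow / w[leave]
        since_refactor <- since_refactor + 1L
      }
    }
  }
  stop("simplex iteration limit reached")
}
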