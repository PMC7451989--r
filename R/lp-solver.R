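## Internal linear-programming core.
##
## All constraint-based computations in this package (FBA, FVA, flux coupling,
## gap filling) reduce to small dense LPs: optimise c'x subject to
## A x {<=,==,>=} b and l <= x <= u.  The solver below is a two-phase
## bounded-variable primal simplex.  Problem sizes in this package are tiny
## (tens of variables), so the basis is refactorised from scratch at every
## iteration; robustness is worth far more here than speed.
##
## Conventions: lower bounds must be finite; upper bounds may be +Inf.
## Status is one of "optimal", "infeasible", "unbounded".

LP_TOL <- 1e-9

#' Solve a linear program
#'
#' Minimises or maximises \code{obj \%*\% x} subject to linear constraints and
#' variable bounds, using a two-phase bounded-variable primal simplex method.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or sparse.
#' @param dir character vector of constraint directions, each one of
#'   \code{"<="}, \code{"=="}, \code{">="}.
#' @param rhs numeric right-hand sides, length m.
#' @param lb,ub variable bounds (recycled); lower bounds must be finite,
#'   upper bounds may be \code{Inf}.
#' @param maximize logical; maximise instead of minimise.
#' @param tol numeric feasibility/pricing tolerance.
#' @return A list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{objval} and \code{x}.
#' @keywords internal
solveLP <- function(obj, A, dir, rhs, lb = 0, ub = Inf,
                    maximize = FALSE, tol = LP_TOL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb)))
    stop("solveLP: all lower bounds must be finite")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objval = NA_real_, x = NULL))

  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  ## slack variables for inequality rows
  nsl <- sum(dir != "==")
  Afull <- cbind(A, matrix(0, m, nsl))
  j <- n
  for (i in seq_len(m)) {
    if (dir[i] == "==") next
    j <- j + 1
    Afull[i, j] <- if (dir[i] == "<=") 1 else -1
  }
  cc <- c(cc, rep(0, nsl))
  lb <- c(lb, rep(0, nsl))
  ub <- c(ub, rep(Inf, nsl))
  ntot <- n + nsl

  res <- simplexBounded(cc, Afull, as.numeric(rhs), lb, ub, tol)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    objval <- sum(as.numeric(obj) * x)
    list(status = "optimal", objval = objval, x = x)
  } else {
    list(status = res$status, objval = NA_real_, x = NULL)
  }
}

## Two-phase bounded simplex for: min c'x  s.t.  A x = b,  l <= x <= u.
simplexBounded <- function(cc, A, b, lb, ub, tol = LP_TOL) {
  m <- nrow(A)
  n <- ncol(A)

  ## phase 1: artificial variables, one per row, initial basis
  xN0 <- lb                       # structurals nonbasic at lower bound
  resid <- b - as.vector(A %*% xN0)
  Sgn <- ifelse(resid >= 0, 1, -1)
  Aph <- cbind(A, diag(Sgn, nrow = m))
  lbp <- c(lb, rep(0, m))
  ubp <- c(ub, rep(Inf, m))
  cph <- c(rep(0, n), rep(1, m))
  basis <- n + seq_len(m)
  atUpper <- rep(FALSE, n + m)    # status of nonbasic variables

  r1 <- simplexIterate(cph, Aph, b, lbp, ubp, basis, atUpper, tol,
                       phase1 = TRUE)
  if (r1$status != "optimal" || r1$objval > 1e-7)
    return(list(status = "infeasible"))
  basis <- r1$basis
  atUpper <- r1$atUpper

  ## pin any artificial still basic (at zero) so it cannot re-enter or move
  art <- n + seq_len(m)
  ubp[art] <- 0

  r2 <- simplexIterate(c(cc, rep(0, m)), Aph, b, lbp, ubp, basis, atUpper,
                       tol, phase1 = FALSE)
  if (r2$status != "optimal")
    return(list(status = r2$status))
  list(status = "optimal", objval = sum(cc * r2$x[seq_len(n)]),
       x = r2$x[seq_len(n)])
}

## Bounded-variable primal simplex iterations from a given feasible basis.
## Dantzig pricing with a Bland's-rule fallback to guarantee termination.
simplexIterate <- function(cc, A, b, lb, ub, basis, atUpper, tol,
                           phase1 = FALSE) {
  m <- nrow(A)
  n <- ncol(A)
  maxit <- 200L + 40L * (n + m)
  blandFrom <- 100L + 10L * (n + m)

  xval <- ifelse(atUpper & is.finite(ub), ub, lb)
  Binv <- solve(A[, basis, drop = FALSE])
  sinceRefactor <- 0L

  for (it in seq_len(maxit)) {
    if (sinceRefactor >= 50L) {       # control numerical drift
      Binv <- solve(A[, basis, drop = FALSE])
      sinceRefactor <- 0L
    }
    nb <- setdiff(seq_len(n), basis)
    xN <- xval[nb]
    An <- A[, nb, drop = FALSE]
    rhsB <- b - as.vector(An %*% xN)
    xB <- as.vector(Binv %*% rhsB)
    xval[basis] <- xB

    y <- as.vector(crossprod(Binv, cc[basis]))
    d <- cc[nb] - as.vector(crossprod(An, y))

    elig <- ((d < -tol & !atUpper[nb]) | (d > tol & atUpper[nb])) &
      (ub[nb] - lb[nb] > tol)                   # fixed variables never enter
    if (!any(elig)) {
      return(list(status = "optimal", x = xval, basis = basis,
                  atUpper = atUpper,
                  objval = sum(cc * xval)))
    }
    cand <- which(elig)
    if (it > blandFrom) {
      qi <- cand[which.min(nb[cand])]           # Bland's rule
    } else {
      qi <- cand[which.max(abs(d[cand]))]       # Dantzig
    }
    q <- nb[qi]
    s <- if (atUpper[q]) -1 else 1              # direction of change of x_q

    w <- as.vector(Binv %*% A[, q])             # x_B = xB - t * s * w
    dirB <- -s * w                              # change in x_B per unit t

    ## ratio test
    tmax <- if (is.finite(ub[q])) ub[q] - lb[q] else Inf
    leave <- 0L                                 # 0 => bound flip
    leaveToUpper <- FALSE
    for (i in seq_len(m)) {
      di <- dirB[i]
      bi <- basis[i]
      if (di < -tol) {                          # basic decreases toward lb
        t_i <- (xB[i] - lb[bi]) / (-di)
        if (t_i < tmax - tol) { tmax <- t_i; leave <- i; leaveToUpper <- FALSE }
        else if (t_i < tmax + tol && leave > 0L && basis[i] < basis[leave]) {
          tmax <- min(tmax, t_i); leave <- i; leaveToUpper <- FALSE
        }
      } else if (di > tol) {                    # basic increases toward ub
        if (!is.finite(ub[bi])) next
        t_i <- (ub[bi] - xB[i]) / di
        if (t_i < tmax - tol) { tmax <- t_i; leave <- i; leaveToUpper <- TRUE }
        else if (t_i < tmax + tol && leave > 0L && basis[i] < basis[leave]) {
          tmax <- min(tmax, t_i); leave <- i; leaveToUpper <- TRUE
        }
      }
    }
    if (!is.finite(tmax)) {
      if (phase1) stop("solveLP: phase-1 unbounded (internal error)")
      return(list(status = "unbounded"))
    }
    tmax <- max(tmax, 0)

    if (leave == 0L) {
      ## entering variable flips to its opposite bound; basis unchanged
      atUpper[q] <- !atUpper[q]
      xval[q] <- if (atUpper[q]) ub[q] else lb[q]
    } else {
      lv <- basis[leave]
      basis[leave] <- q
      atUpper[lv] <- leaveToUpper
      xval[lv] <- if (leaveToUpper) ub[lv] else lb[lv]
      xval[q] <- xval[q] + s * tmax
      atUpper[q] <- FALSE
      if (abs(w[leave]) < 1e-11) {              # degenerate pivot: refactor
        Binv <- solve(A[, basis, drop = FALSE])
        sinceRefactor <- 0L
      } else {                                  # eta update of the inverse
        er <- numeric(m); er[leave] <- 1
        Binv <- Binv - outer((w - er) / w[leave], Binv[leave, ])
        sinceRefactor <- sinceRefactor + 1L
      }
    }
  }
  stop("solveLP: iteration limit reached")
}

#' Solve a mixed-integer linear program with binary variables
#'
#' Depth-first branch and bound over a set of binary variables, with the
#' bounded-simplex LP relaxation as the bounding function. Designed for the
#' small cardinality-minimisation problems arising in gap filling.
#'
#' @inheritParams solveLP
#' @param binary integer indices of variables restricted to \{0, 1\}.
#' @param inttol integrality tolerance; must be smaller than the smallest
#'   meaningful fractional activation (threshold / big-M) or weak LP
#'   relaxations leak through as spuriously integral.
#' @return As \code{\link{solveLP}}; \code{status} is \code{"optimal"} or
#'   \code{"infeasible"} (binaries make unboundedness impossible for the
#'   bounded objectives used here).
#' @keywords internal
solveMILP <- function(obj, A, dir, rhs, lb = 0, ub = Inf, binary = integer(),
                      maximize = FALSE, inttol = 1e-7) {
  n <- ncol(A)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  lb[binary] <- pmax(lb[binary], 0)
  ub[binary] <- pmin(ub[binary], 1)

  sgn <- if (maximize) -1 else 1
  best <- list(objval = Inf, x = NULL)

  recurse <- function(lo, hi) {
    rel <- solveLP(sgn * obj, A, dir, rhs, lo, hi, maximize = FALSE)
    if (rel$status != "optimal") return(invisible(NULL))
    if (rel$objval >= best$objval - inttol) return(invisible(NULL))
    xb <- rel$x[binary]
    frac <- abs(xb - round(xb))
    if (length(binary) == 0L || max(frac) <= inttol) {
      best <<- list(objval = rel$objval, x = rel$x)
      return(invisible(NULL))
    }
    jb <- binary[which.max(frac)]
    ## explore the 0-branch first: favours small activated sets
    lo0 <- lo; hi0 <- hi; hi0[jb] <- 0
    recurse(lo0, hi0)
    lo1 <- lo; hi1 <- hi; lo1[jb] <- 1
    recurse(lo1, hi1)
    invisible(NULL)
  }
  recurse(lb, ub)

  if (is.null(best$x))
    return(list(status = "infeasible", objval = NA_real_, x = NULL))
  list(status = "optimal", objval = sgn * best$objval, x = best$x)
}
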