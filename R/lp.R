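# Dense two-phase simplex for the small equality-constrained, box-bounded
# linear programs that flux balance and flux variability analysis generate.
# Problem sizes here are tiny (tens of variables), so a dense tableau with
# Bland's anti-cycling rule is both adequate and fully deterministic.

#' Solve a box-bounded linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `Aeq %*% x == beq` and
#' `lb <= x <= ub`, using a dense two-phase simplex with Bland's rule.
#'
#' @param obj numeric objective coefficient vector.
#' @param Aeq equality constraint matrix (may have zero rows).
#' @param beq equality right-hand side.
#' @param lb,ub finite lower bounds and (possibly infinite) upper bounds.
#' @param maximize logical; maximize instead of minimize.
#' @param tol feasibility/optimality tolerance.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution, `NA` unless optimal) and `objective`.
#' @export
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), ncol = n)
  stopifnot(length(beq) == nrow(Aeq), length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) {
    stop("lp_solve requires finite lower bounds; use a large negative bound instead")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  cost <- if (maximize) -obj else obj

  m <- nrow(Aeq)
  d <- ub - lb                      # shifted variable ranges, y = x - lb
  bounded <- which(is.finite(d))
  k <- length(bounded)

  # columns: y (n), slacks for finite upper bounds (k), artificials (m)
  ncol_tot <- n + k + m
  nrow_tot <- m + k
  A <- matrix(0, nrow_tot, ncol_tot)
  b <- numeric(nrow_tot)
  if (m > 0) {
    A[seq_len(m), seq_len(n)] <- Aeq
    b[seq_len(m)] <- beq - as.numeric(Aeq %*% lb)
  }
  if (k > 0) {
    for (j in seq_len(k)) {
      A[m + j, bounded[j]] <- 1
      A[m + j, n + j] <- 1
      b[m + j] <- d[bounded[j]]
    }
  }
  # make rhs nonnegative (only equality rows can be negative)
  neg <- which(b < 0)
  if (length(neg)) {
    A[neg, ] <- -A[neg, ]
    b[neg] <- -b[neg]
  }
  # artificial columns for equality rows; slack columns start feasible for
  # the bound rows, so they serve as the initial basis there
  basis <- integer(nrow_tot)
  if (m > 0) {
    for (i in seq_len(m)) {
      A[i, n + k + i] <- 1
      basis[i] <- n + k + i
    }
  }
  if (k > 0) basis[m + seq_len(k)] <- n + seq_len(k)

  tab <- cbind(A, b)

  # phase 1: minimize sum of artificials
  if (m > 0) {
    c1 <- c(rep(0, n + k), rep(1, m))
    tab <- rbind(tab, .lp_cost_row(tab, basis, c1, ncol_tot))
    res <- .lp_iterate(tab, basis, ncol_tot, tol)
    tab <- res$tab; basis <- res$basis
    p1 <- -tab[nrow(tab), ncol_tot + 1]
    if (res$status != "optimal" || p1 > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
    }
    tab <- tab[-nrow(tab), , drop = FALSE]
    # drive residual basic artificials out, or drop redundant rows
    keep <- rep(TRUE, nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (basis[i] > n + k) {
        piv <- which(abs(tab[i, seq_len(n + k)]) > 1e-9)
        if (length(piv)) {
          tab <- .lp_pivot(tab, i, piv[1])
          basis[i] <- piv[1]
        } else {
          keep[i] <- FALSE
        }
      }
    }
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
  }
  # drop artificial columns
  tab <- tab[, c(seq_len(n + k), ncol_tot + 1), drop = FALSE]
  ncol_tot <- n + k

  # phase 2
  c2 <- c(cost, rep(0, k))
  tab <- rbind(tab, .lp_cost_row(tab, basis, c2, ncol_tot))
  res <- .lp_iterate(tab, basis, ncol_tot, tol)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  if (res$status != "optimal") {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  tab <- res$tab; basis <- res$basis
  y <- numeric(ncol_tot)
  y[basis] <- tab[seq_len(nrow(tab) - 1), ncol_tot + 1]
  x <- y[seq_len(n)] + lb
  list(status = "optimal", x = x, objective = sum(obj * x))
}

.lp_cost_row <- function(tab, basis, cost, ncol_tot) {
  row <- c(cost, 0)
  for (i in seq_along(basis)) {
    cb <- cost[basis[i]]
    if (cb != 0) row <- row - cb * tab[i, ]
  }
  row
}

.lp_pivot <- function(tab, pr, pc) {
  tab[pr, ] <- tab[pr, ] / tab[pr, pc]
  other <- setdiff(seq_len(nrow(tab)), pr)
  fac <- tab[other, pc]
  nz <- which(fac != 0)
  if (length(nz)) {
    tab[other[nz], ] <- tab[other[nz], , drop = FALSE] -
      outer(fac[nz], tab[pr, ])
  }
  tab
}

.lp_iterate <- function(tab, basis, ncol_tot, tol, maxit = 20000L) {
  m <- nrow(tab) - 1L
  for (it in seq_len(maxit)) {
    rc <- tab[m + 1L, seq_len(ncol_tot)]
    ent <- which(rc < -tol)
    if (!length(ent)) return(list(tab = tab, basis = basis, status = "optimal"))
    pc <- ent[1L]                               # Bland: smallest index enters
    col <- tab[seq_len(m), pc]
    pos <- which(col > tol)
    if (!length(pos)) return(list(tab = tab, basis = basis, status = "unbounded"))
    ratio <- tab[pos, ncol_tot + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    pr <- cand[which.min(basis[cand])]          # Bland: smallest basic leaves
    tab <- .lp_pivot(tab, pr, pc)
    basis[pr] <- pc
  }
  list(tab = tab, basis = basis, status = "maxit")
}

#' Enumerate the vertices of a flux polytope by brute force
#'
#' Exhaustively enumerates basic feasible solutions of
#' `{x : Aeq x = beq, lb <= x <= ub}`. Intended as an independent oracle for
#' linear-programming results on small fixtures (at most ~8 free fluxes);
#' cost grows combinatorially with dimension.
#'
#' @inheritParams lp_solve
#' @param tol feasibility tolerance for accepting a candidate vertex.
#' @return matrix with one vertex per row (zero rows if infeasible).
#' @export
enumerate_vertices <- function(Aeq, beq, lb, ub, tol = 1e-8) {
  n <- length(lb)
  Aeq <- matrix(as.numeric(Aeq), ncol = n)
  qrA <- qr(t(Aeq))
  r <- qrA$rank
  free <- n - r
  if (free > 12) stop("vertex enumeration limited to <= 12 free fluxes")
  verts <- list()
  bases <- utils::combn(n, r, simplify = FALSE)
  for (B in bases) {
    AB <- Aeq[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    if (!length(N)) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      xN <- ifelse(unlist(grid[g, ], use.names = FALSE), ub[N], lb[N])
      if (any(!is.finite(xN))) next
      rhs <- beq - if (length(N)) as.numeric(Aeq[, N, drop = FALSE] %*% xN) else beq * 0
      xB <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n)
      x[B] <- xB
      x[N] <- xN
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(Aeq %*% x - beq)) > tol * (1 + max(abs(beq)))) next
      verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 7)), , drop = FALSE]
}
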