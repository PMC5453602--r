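# Internal dense two-phase simplex solver.
#
# Solves   min/max  obj'v
#          s.t.     A_eq v  = b_eq
#                   A_ub v <= b_ub
#                   lb <= v <= ub        (lb finite; ub may be +Inf)
#
# All flux-balance problems in this package are small and dense (tens of
# reactions), so a full-tableau simplex is both adequate and dependency-free.
# Phase 1 minimises the sum of artificial variables; phase 2 optimises the
# user objective. Dantzig pricing with a switch to Bland's rule guards
# against cycling on degenerate vertices.
#
# Returns list(status = "optimal"|"infeasible"|"unbounded", objective, x).
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = FALSE,
                     tol = 1e-9, feas_tol = 1e-7) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("lp_solve requires finite lower bounds")
  if (any(lb > ub + 1e-9)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  ub <- pmax(ub, lb)

  A_eq <- if (is.null(A_eq)) matrix(0, 0, n) else as.matrix(A_eq)
  b_eq <- if (is.null(b_eq)) numeric(0) else as.numeric(b_eq)
  A_ub <- if (is.null(A_ub)) matrix(0, 0, n) else as.matrix(A_ub)
  b_ub <- if (is.null(b_ub)) numeric(0) else as.numeric(b_ub)

  # shift x = v - lb >= 0
  m_eq <- nrow(A_eq); m_ub <- nrow(A_ub)
  beq <- b_eq - if (m_eq) as.vector(A_eq %*% lb) else numeric(0)
  bub <- b_ub - if (m_ub) as.vector(A_ub %*% lb) else numeric(0)
  fin <- which(is.finite(ub))
  u <- ub[fin] - lb[fin]

  # columns: n structural + m_ub inequality slacks + |fin| bound slacks
  K <- n + m_ub + length(fin)
  M <- m_eq + m_ub + length(fin)
  A <- matrix(0, M, K)
  b <- numeric(M)
  if (m_eq) { A[seq_len(m_eq), seq_len(n)] <- A_eq; b[seq_len(m_eq)] <- beq }
  if (m_ub) {
    r <- m_eq + seq_len(m_ub)
    A[r, seq_len(n)] <- A_ub
    A[cbind(r, n + seq_len(m_ub))] <- 1
    b[r] <- bub
  }
  if (length(fin)) {
    r <- m_eq + m_ub + seq_along(fin)
    A[cbind(r, fin)] <- 1
    A[cbind(r, n + m_ub + seq_along(fin))] <- 1
    b[r] <- u
  }
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  cvec <- numeric(K)
  cvec[seq_len(n)] <- if (maximize) -obj else obj

  # ---- phase 1 ----
  Tb <- cbind(A, diag(M), b)
  basis <- K + seq_len(M)
  cost1 <- c(rep(0, K), rep(1, M))
  # reduced-cost row for phase-1 basis (all artificial): r = c - 1'A
  rrow <- c(-colSums(A), rep(0, M), -sum(b))
  Tb <- rbind(Tb, rrow)
  res <- simplex_iterate(Tb, basis, ncols = K + M, tol = tol)
  if (res$status == "unbounded")
    stop("internal error: phase-1 LP unbounded")  # cannot happen: cost bounded below by 0
  Tb <- res$Tb; basis <- res$basis
  phase1_obj <- -Tb[nrow(Tb), ncol(Tb)]
  if (phase1_obj > feas_tol * max(1, max(abs(b)))) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }

  # drive remaining artificials out of the basis (degenerate pivots), or drop
  # redundant rows
  keep <- rep(TRUE, M)
  for (i in seq_len(M)) {
    if (basis[i] > K) {
      piv <- which(abs(Tb[i, seq_len(K)]) > tol)
      if (length(piv)) {
        Tb <- pivot_tableau(Tb, i, piv[1])
        basis[i] <- piv[1]
      } else {
        keep[i] <- FALSE
      }
    }
  }
  rows <- c(which(keep), nrow(Tb))
  Tb <- Tb[rows, c(seq_len(K), ncol(Tb)), drop = FALSE]
  basis <- basis[keep]
  M2 <- length(basis)

  # ---- phase 2 ----
  cb <- cvec[basis]
  body <- Tb[seq_len(M2), seq_len(K), drop = FALSE]
  rhs <- Tb[seq_len(M2), K + 1]
  rrow <- c(cvec - as.vector(crossprod(cb, body)), -sum(cb * rhs))
  Tb[nrow(Tb), ] <- rrow
  res <- simplex_iterate(Tb, basis, ncols = K, tol = tol)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  }
  Tb <- res$Tb; basis <- res$basis
  z <- numeric(K)
  z[basis] <- Tb[seq_len(length(basis)), ncol(Tb)]
  v <- z[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), x = v)
}

# one simplex phase on tableau Tb ((M+1) x (ncols+1); last row = reduced
# costs, last column = RHS). Minimisation; entering variable has reduced
# cost < -tol. Returns updated tableau/basis and a status.
simplex_iterate <- function(Tb, basis, ncols, tol = 1e-9, max_iter = 20000L) {
  M <- nrow(Tb) - 1L
  bland_after <- 4L * (ncols + M)
  for (it in seq_len(max_iter)) {
    r <- Tb[M + 1L, seq_len(ncols)]
    if (it <= bland_after) {
      j <- which.min(r)
      if (r[j] >= -tol) return(list(status = "optimal", Tb = Tb, basis = basis))
    } else {
      cand <- which(r < -tol)  # Bland: lowest index, guarantees termination
      if (!length(cand)) return(list(status = "optimal", Tb = Tb, basis = basis))
      j <- cand[1]
    }
    col <- Tb[seq_len(M), j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
    ratio <- Tb[pos, ncol(Tb)] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol * (1 + rmin)]
    i <- ties[which.min(basis[ties])]
    Tb <- pivot_tableau(Tb, i, j)
    basis[i] <- j
  }
  stop("simplex iteration limit exceeded")
}

pivot_tableau <- function(Tb, i, j) {
  prow <- Tb[i, ] / Tb[i, j]
  col <- Tb[, j]
  Tb <- Tb - outer(col, prow)
  Tb[i, ] <- prow
  Tb[, j] <- 0
  Tb[i, j] <- 1
  Tb
}
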