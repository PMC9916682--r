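# Internal linear-programming layer.
#
# All LPs in the package (flux balance analysis, feasibility certificates,
# bound relaxation, interior-point search for the sampler) are routed
# through solve_lp_core(), a self-contained two-phase tableau simplex with
# a Dantzig pivot rule falling back to Bland's anti-cycling rule. The
# problems here are small (tens to ~150 variables), dense, and often carry
# degenerate vertices from lumped stoichiometry, so robustness matters more
# than speed; correctness is cross-checked in the test suite against a
# brute-force vertex-enumeration oracle.

# Solve max/min obj'x s.t. A_eq x = b_eq, A_ub x <= b_ub, x >= 0.
# Returns list(status, x, value); status "optimal" | "infeasible" |
# "unbounded" | "iteration_limit".
solve_lp_core <- function(obj, A_eq = NULL, b_eq = NULL,
                          A_ub = NULL, b_ub = NULL, maxi = TRUE,
                          n_iter = NULL, tol = 1e-9) {
  n <- length(obj)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_ub)) { A_ub <- matrix(0, 0, n); b_ub <- numeric(0) }
  m_ub <- nrow(A_ub); m_eq <- nrow(A_eq)

  # standard form: [A_ub | I_slack] , [A_eq | 0]; flip rows to b >= 0
  A <- rbind(cbind(A_ub, diag(1, m_ub)),
             cbind(A_eq, matrix(0, m_eq, m_ub)))
  b <- c(as.vector(b_ub), as.vector(b_eq))
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  m <- m_ub + m_eq
  n_tot <- n + m_ub

  # initial basis: slack where usable (<= row, not flipped), else artificial
  slack_ok <- c(!flip[seq_len(m_ub)], rep(FALSE, m_eq))
  n_art <- sum(!slack_ok)
  if (n_art > 0) {
    Art <- matrix(0, m, n_art)
    Art[cbind(which(!slack_ok), seq_len(n_art))] <- 1
    A <- cbind(A, Art)
  }
  basis <- integer(m)
  basis[slack_ok] <- n + which(slack_ok[seq_len(m_ub)])
  basis[!slack_ok] <- n_tot + seq_len(n_art)

  ncol_A <- ncol(A)
  if (is.null(n_iter)) n_iter <- max(500L, 60L * (m + ncol_A))

  T_ <- cbind(A, b)  # working tableau rows; cost rows handled separately
  # reduce so basic columns are identity
  for (i in seq_len(m)) {
    piv <- T_[i, basis[i]]
    if (abs(piv - 1) > tol) T_[i, ] <- T_[i, ] / piv
  }

  run_simplex <- function(T_, basis, cost, n_iter, bland_after = 200L) {
    m <- nrow(T_); nc <- ncol(T_) - 1L
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > n_iter) return(list(T_ = T_, basis = basis,
                                   status = "iteration_limit"))
      cb <- cost[basis]
      # reduced costs (minimization): r_j = c_j - cb' B^-1 A_j
      red <- cost[seq_len(nc)] -
        as.vector(crossprod(T_[, seq_len(nc), drop = FALSE], cb))
      red[basis] <- 0
      cand <- which(red < -tol)
      if (!length(cand))
        return(list(T_ = T_, basis = basis, status = "optimal"))
      j <- if (it > bland_after) cand[1L] else cand[which.min(red[cand])]
      col <- T_[, j]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(T_ = T_, basis = basis, status = "unbounded"))
      ratio <- T_[pos, nc + 1L] / col[pos]
      r_min <- min(ratio)
      ties <- pos[ratio <= r_min + tol]
      i <- ties[which.min(basis[ties])]  # Bland-style leaving tie-break
      # pivot
      T_[i, ] <- T_[i, ] / T_[i, j]
      other <- setdiff(seq_len(m), i)
      T_[other, ] <- T_[other, , drop = FALSE] -
        outer(T_[other, j], T_[i, ])
      basis[i] <- j
    }
  }

  if (n_art > 0) {
    cost1 <- c(rep(0, n_tot), rep(1, n_art))
    ph1 <- run_simplex(T_, basis, cost1, n_iter)
    if (ph1$status != "optimal")
      return(list(status = if (ph1$status == "unbounded") "infeasible"
                           else ph1$status, x = NULL, value = NA_real_))
    T_ <- ph1$T_; basis <- ph1$basis
    if (sum(T_[basis > n_tot, ncol(T_)]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # drive residual (degenerate) artificials out of the basis
    for (i in which(basis > n_tot)) {
      row <- T_[i, seq_len(n_tot)]
      j <- which(abs(row) > tol)[1]
      if (is.na(j)) next  # redundant row; leave harmless artificial at 0
      T_[i, ] <- T_[i, ] / T_[i, j]
      other <- setdiff(seq_len(m), i)
      T_[other, ] <- T_[other, , drop = FALSE] - outer(T_[other, j], T_[i, ])
      basis[i] <- j
    }
    # forbid artificials re-entering by truncating them away
    keep_rows <- basis <= n_tot
    T_ <- T_[keep_rows, c(seq_len(n_tot), ncol(T_)), drop = FALSE]
    basis <- basis[keep_rows]
  }

  cost2 <- if (maxi) -c(obj, rep(0, n_tot - n)) else c(obj, rep(0, n_tot - n))
  ph2 <- run_simplex(T_, basis, cost2, n_iter)
  if (ph2$status != "optimal")
    return(list(status = ph2$status, x = NULL, value = NA_real_))
  x_full <- numeric(n_tot)
  x_full[ph2$basis] <- ph2$T_[, ncol(ph2$T_)]
  x <- x_full[seq_len(n)]
  list(status = "optimal", x = x, value = sum(obj * x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rows of S forming a full-row-rank subsystem; stoichiometric matrices
# often carry conserved-moiety rows that are linear combinations of others,
# and redundant equalities only add degenerate pivots.
independent_rows <- function(S) {
  qrt <- qr(t(S))
  sort(qrt$pivot[seq_len(qrt$rank)])
}

# Solve max/min c'v s.t. S v = 0, lb <= v <= ub (shifts v = x + lb).
solve_flux_lp <- function(cvec, S, lb, ub, maxi = TRUE) {
  stopifnot(length(cvec) == ncol(S), all(lb <= ub))
  S <- S[independent_rows(S), , drop = FALSE]
  n <- ncol(S)
  res <- solve_lp_core(obj = cvec,
                       A_eq = S, b_eq = as.vector(-S %*% lb),
                       A_ub = diag(n), b_ub = ub - lb,
                       maxi = maxi)
  if (res$status == "optimal") {
    v <- res$x + lb
    res$x <- v
    res$value <- sum(cvec * v)
  }
  res
}

# Minimal-total-slack LP: find v, s_lo >= 0, s_up >= 0 minimising
# sum(s_lo) + sum(s_up) s.t. S v = 0, lb - s_lo <= v <= ub + s_up, where
# slack variables exist only for reactions in `slack_idx`. Substituting
# y = v - lb + s_lo (>= 0) yields a standard-form LP.
# Returns list(status, v, slack_lower, slack_upper, total_slack).
solve_slack_lp <- function(S, lb, ub, slack_idx = seq_len(ncol(S))) {
  S <- S[independent_rows(S), , drop = FALSE]
  n <- ncol(S)
  k <- length(slack_idx)
  Ssel <- S[, slack_idx, drop = FALSE]
  # variables: y (n), s_lo (k), s_up (k)
  obj <- c(rep(0, n), rep(1, 2 * k))
  A_eq <- cbind(S, -Ssel, matrix(0, nrow(S), k))
  b_eq <- as.vector(-S %*% lb)
  # y_i - s_lo_i - s_up_i <= ub_i - lb_i (slack cols only on slack_idx rows)
  E_lo <- matrix(0, n, k); E_lo[cbind(slack_idx, seq_len(k))] <- 1
  A_ub <- cbind(diag(n), -E_lo, -E_lo)
  b_ub <- ub - lb
  res <- solve_lp_core(obj, A_eq, b_eq, A_ub, b_ub, maxi = FALSE)
  if (res$status != "optimal") {
    return(list(status = res$status, v = NULL,
                slack_lower = NULL, slack_upper = NULL,
                total_slack = NA_real_))
  }
  y <- res$x[seq_len(n)]
  s_lo_sel <- res$x[n + seq_len(k)]
  s_up_sel <- res$x[n + k + seq_len(k)]
  s_lo <- numeric(n); s_lo[slack_idx] <- s_lo_sel
  s_up <- numeric(n); s_up[slack_idx] <- s_up_sel
  v <- y + lb - s_lo
  list(status = "optimal", v = v,
       slack_lower = s_lo, slack_upper = s_up,
       total_slack = sum(s_lo) + sum(s_up))
}
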