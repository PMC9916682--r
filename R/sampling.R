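# Constraint-respecting random flux sampling.
#
# Hit-and-run over the steady-state polytope {v : S v = 0, lb <= v <= ub},
# run in null-space coordinates so every iterate satisfies S v = 0 exactly
# (up to the null-space basis accuracy). Reactions are canonically sorted by
# id before the basis is built, so the sample set is invariant to the input
# reaction ordering up to column relabeling.

#' Sample flux vectors from the steady-state polytope
#'
#' Seeded hit-and-run sampler. The walk starts at an interior point found by
#' maximising the minimum relative bound margin (a Chebyshev-centre LP in
#' null-space coordinates), performs `warmup` discarded steps (default
#' `100 * n_reactions`), then records every `thin`-th iterate.
#'
#' Identical seeds give bit-identical sample matrices.
#'
#' @param net a feasible `MetabolicNetwork`.
#' @param n_samples number of flux vectors to return (>= 1).
#' @param seed integer RNG seed (mandatory, for reproducibility).
#' @param warmup number of discarded warm-up steps; default
#'   `100 * n_reactions`.
#' @param thin keep every `thin`-th step after warm-up (default 10).
#' @return a `FluxSampleSet`: list with `samples` (n_samples x n_reactions
#'   matrix, columns named by reaction id), `sampler`, `seed`, `warmup`,
#'   `thin`.
#' @export
sample_fluxes <- function(net, n_samples, seed, warmup = NULL, thin = 10) {
  stopifnot(n_samples >= 1)
  if (missing(seed)) stop("seed is mandatory")
  bad <- infeasible_bounds(net)
  if (length(bad)) stop("infeasible by bounds: ", paste(bad, collapse = ", "))

  ord <- order(net$reactions$id)
  S <- stoich_matrix(net)[, ord, drop = FALSE]
  lb <- net$reactions$lb[ord]
  ub <- net$reactions$ub[ord]
  n <- ncol(S)
  if (is.null(warmup)) warmup <- 100L * n

  # orthonormal null-space basis of S
  sv <- svd(S, nu = 0, nv = n)
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  N <- sv$v[, seq(rank + 1L, n), drop = FALSE]
  if (ncol(N) == 0L) {
    # zero-dimensional polytope: the only candidate is v = 0 projected onto
    # bounds; check feasibility of v = 0
    v0 <- numeric(n)
    if (any(v0 < lb - TOL_FEAS | v0 > ub + TOL_FEAS))
      stop("network has a zero-dimensional infeasible flux space")
    out <- matrix(rep(v0, n_samples), nrow = n_samples, byrow = TRUE)
  } else {
    start <- interior_point(N, lb, ub)
    if (is.null(start))
      stop("failed to find an interior starting point (network infeasible?)")
    set.seed(as.integer(seed))
    d_dim <- ncol(N)
    total <- warmup + thin * n_samples
    out <- matrix(NA_real_, n_samples, n)
    t_cur <- start$t
    v_cur <- as.vector(N %*% t_cur)
    kept <- 0L
    for (step in seq_len(total)) {
      dir_t <- stats::rnorm(d_dim)
      dir_t <- dir_t / sqrt(sum(dir_t^2))
      w <- as.vector(N %*% dir_t)
      # step interval [a_lo, a_hi] keeping lb <= v + a w <= ub
      pos <- w > 1e-12
      neg <- w < -1e-12
      a_hi <- min(c((ub[pos] - v_cur[pos]) / w[pos],
                    (lb[neg] - v_cur[neg]) / w[neg], Inf))
      a_lo <- max(c((lb[pos] - v_cur[pos]) / w[pos],
                    (ub[neg] - v_cur[neg]) / w[neg], -Inf))
      if (!is.finite(a_hi) || !is.finite(a_lo)) {
        a_hi <- min(a_hi, 1e6); a_lo <- max(a_lo, -1e6)
      }
      if (a_hi > a_lo) {
        a <- stats::runif(1, a_lo, a_hi)
        t_cur <- t_cur + a * dir_t
        v_cur <- v_cur + a * w
      }
      if (step > warmup && (step - warmup) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- v_cur
      }
    }
  }
  colnames(out) <- net$reactions$id[ord]
  out <- out[, net$reactions$id, drop = FALSE]  # restore input order
  structure(list(samples = out, sampler = "hit-and-run", seed = seed,
                 warmup = warmup, thin = thin),
            class = "FluxSampleSet")
}

# Chebyshev-style interior point in null-space coordinates: maximise e with
# lb + e*r <= N t <= ub - e*r, r_i = ||N_i.|| (rows with r ~ 0 are fixed and
# get no margin). Solved with t boxed in [-TBOX, TBOX].
interior_point <- function(N, lb, ub, TBOX = 1e4) {
  n <- nrow(N); k <- ncol(N)
  r <- sqrt(rowSums(N^2))
  r[r < 1e-10] <- 0
  e_cap <- max(ub - lb) / 2 + 1
  # vars: tt (k, = t + TBOX >= 0), e (1)
  obj <- c(rep(0, k), 1)
  shift <- as.vector(N %*% rep(TBOX, k))
  # substituting t = tt - TBOX (tt >= 0):
  #   N t + e r <= ub   ->   N tt + e r <= ub + shift
  #   N t - e r >= lb   ->  -N tt + e r <= -lb - shift
  A_ub <- rbind(cbind(N, r),
                cbind(-N, r),
                c(rep(0, k), 1))        # e <= e_cap
  b_ub <- c(ub + shift, -lb - shift, e_cap)
  res <- solve_lp_core(obj, A_ub = A_ub, b_ub = b_ub, maxi = TRUE)
  if (res$status != "optimal") return(NULL)
  tt <- res$x[seq_len(k)]
  e <- res$x[k + 1L]
  t0 <- tt - TBOX
  v0 <- as.vector(N %*% t0)
  if (any(v0 < lb - TOL_FEAS) || any(v0 > ub + TOL_FEAS)) return(NULL)
  list(t = t0, v = v0, margin = e)
}

#' @export
print.FluxSampleSet <- function(x, ...) {
  cat("<FluxSampleSet> ", nrow(x$samples), " samples x ",
      ncol(x$samples), " reactions (", x$sampler,
      ", seed ", x$seed, ", warmup ", x$warmup, ", thin ", x$thin, ")\n",
      sep = "")
  invisible(x)
}

#' Verify sampled fluxes against network invariants
#'
#' Checks every sampled row for steady state (`max |S v| <= tol`) and bound
#' satisfaction.
#'
#' @param sample_set a `FluxSampleSet`.
#' @param net the network it was sampled from.
#' @param tol feasibility tolerance.
#' @return logical vector, one entry per sample.
#' @export
samples_feasible <- function(sample_set, net, tol = TOL_FEAS) {
  S <- stoich_matrix(net)
  V <- sample_set$samples[, colnames(S), drop = FALSE]
  resid <- apply(abs(S %*% t(V)), 2, max)
  inb <- apply(V, 1, function(v)
    all(v >= net$reactions$lb - tol & v <= net$reactions$ub + tol))
  resid <= tol & inb
}
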