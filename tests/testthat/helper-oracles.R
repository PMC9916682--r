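# Shared fixtures and independent oracles.

# Brute-force LP oracle: enumerate candidate vertices of
# {v : S v = 0, lb <= v <= ub} by fixing (n - rank) coordinates at a bound
# and solving the equality system for the rest; return the optimal
# objective over feasible vertices. Only for tiny networks (n <= ~8).
vertex_lp_oracle <- function(cvec, S, lb, ub, maxi = TRUE) {
  keep <- {
    qrt <- qr(t(S))
    sort(qrt$pivot[seq_len(qrt$rank)])
  }
  S <- S[keep, , drop = FALSE]
  n <- ncol(S); r <- nrow(S); free <- n - r
  best <- NULL
  combs <- if (free == 0) list(integer(0))
           else utils::combn(n, free, simplify = FALSE)
  for (fix in combs) {
    rest <- setdiff(seq_len(n), fix)
    if (length(rest)) {
      Sr <- S[, rest, drop = FALSE]
      if (abs(det(Sr)) < 1e-10) next
    }
    grid <- if (length(fix))
      expand.grid(rep(list(c(1, 2)), length(fix))) else data.frame(x = 1)
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(fix))
        v[fix] <- ifelse(unlist(grid[g, , drop = FALSE]) == 1,
                         lb[fix], ub[fix])[seq_along(fix)]
      if (length(rest))
        v[rest] <- solve(Sr, -S %*% replace(numeric(n), fix, v[fix]))
      if (all(v >= lb - 1e-8 & v <= ub + 1e-8)) {
        val <- sum(cvec * v)
        if (is.null(best) || (maxi && val > best) || (!maxi && val < best))
          best <- val
      }
    }
  }
  best
}

fba_oracle <- function(net, objective_id, maxi = TRUE) {
  cvec <- as.numeric(net$reactions$id == objective_id)
  vertex_lp_oracle(cvec, stoich_matrix(net),
                   net$reactions$lb, net$reactions$ub, maxi = maxi)
}

# Linear chain A_e -> A -> B -> B_e with an exchange at each end.
chain_network <- function(ex_a = c(-10, 0), r1 = c(0, 1000),
                          ex_b = c(0, 1000)) {
  metabolic_network(
    "chain",
    metabolites = data.frame(id = c("A_e", "A", "B", "B_e"),
                             compartment = c("e", "c", "c", "e")),
    reactions = data.frame(
      id = c("EX_A", "T1", "R1", "T2", "EX_B"),
      lb = c(ex_a[1], 0, r1[1], 0, ex_b[1]),
      ub = c(ex_a[2], 1000, r1[2], 1000, ex_b[2])),
    stoich = list(EX_A = c(A_e = -1), T1 = c(A_e = -1, A = 1),
                  R1 = c(A = -1, B = 1), T2 = c(B = -1, B_e = 1),
                  EX_B = c(B_e = -1)))
}

# One-dimensional flux polytope: every reaction carries the same flux,
# bounded to [2, 6].
polytope_1d_network <- function() {
  metabolic_network(
    "poly1d",
    metabolites = data.frame(id = c("A_e", "A", "B_e"),
                             compartment = c("e", "c", "e")),
    reactions = data.frame(id = c("EX_A", "T1", "EX_B"),
                           lb = c(-6, 2, 2), ub = c(-2, 6, 6)),
    stoich = list(EX_A = c(A_e = -1), T1 = c(A_e = -1, A = 1),
                  EX_B = c(A = -1)))
}

# All partitions of seq_len(n) into exactly k labelled-free blocks.
set_partitions_k <- function(n, k) {
  out <- list()
  recurse <- function(i, blocks) {
    if (i > n) {
      if (length(blocks) == k) out[[length(out) + 1L]] <<- blocks
      return(invisible())
    }
    if (length(blocks) + (n - i + 1) < k) return(invisible())
    for (b in seq_along(blocks)) {
      nb <- blocks; nb[[b]] <- c(nb[[b]], i)
      recurse(i + 1, nb)
    }
    if (length(blocks) < k) recurse(i + 1, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  out
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
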