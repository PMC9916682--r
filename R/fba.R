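# Flux balance analysis and feasibility certificates.

TOL_FEAS <- 1e-6

#' Flux balance analysis
#'
#' Solves the linear program `max (or min) v_obj  s.t.  S v = 0,
#' lb <= v <= ub` and returns the optimal flux vector. Degenerate alternate
#' optima are possible; one optimal vertex is returned and downstream code
#' must rely only on the objective value or on sampled distributions.
#'
#' A reaction whose declared bound was infinite is solved at the network's
#' finite cap; if the optimum pins the objective reaction against such an
#' artificial cap the status is reported as `"unbounded"`.
#'
#' @param net a `MetabolicNetwork`.
#' @param objective_id reaction id to optimize; defaults to the network's
#'   stored objective.
#' @param direction `"max"` or `"min"`.
#' @return a `FluxVector`: list with `fluxes` (named numeric), `objective`
#'   (optimal value), `status` (`"optimal"`, `"infeasible"`,
#'   `"infeasible_by_bounds"`, `"unbounded"`).
#' @export
fba <- function(net, objective_id = NULL, direction = NULL) {
  if (is.null(objective_id)) {
    if (is.null(net$objective)) stop("no objective given or stored")
    objective_id <- net$objective$reaction
    direction <- direction %||% net$objective$direction
  }
  direction <- match.arg(direction %||% "max", c("max", "min"))
  idx <- match(objective_id, net$reactions$id)
  if (is.na(idx)) stop("unknown objective reaction: ", objective_id)
  bad <- infeasible_bounds(net)
  if (length(bad)) {
    return(flux_vector(net, NULL, NA_real_, "infeasible_by_bounds",
                       detail = bad))
  }
  S <- stoich_matrix(net)
  cvec <- numeric(ncol(S)); cvec[idx] <- 1
  res <- solve_flux_lp(cvec, S, net$reactions$lb, net$reactions$ub,
                       maxi = direction == "max")
  if (res$status != "optimal")
    return(flux_vector(net, NULL, NA_real_, res$status))
  status <- "optimal"
  if (objective_id %in% net$clamped) {
    v <- res$x[idx]
    cap <- net$bound_cap
    if (abs(abs(v) - cap) <= 1e-6 * cap) status <- "unbounded"
  }
  flux_vector(net, res$x, res$value, status)
}

flux_vector <- function(net, v, objective, status, detail = NULL) {
  structure(list(
    fluxes = if (!is.null(v)) stats::setNames(v, net$reactions$id),
    objective = objective,
    status = status,
    detail = detail
  ), class = "FluxVector")
}

#' @export
print.FluxVector <- function(x, ...) {
  cat("<FluxVector> status: ", x$status,
      "  objective: ", format(x$objective), "\n", sep = "")
  invisible(x)
}

#' Feasibility report for a metabolic network
#'
#' Reports whether the steady-state polytope `{v : S v = 0, lb <= v <= ub}`
#' is nonempty. For bound-inconsistent networks (`lb > ub` somewhere) the
#' offending reactions are named. For bound-consistent but infeasible
#' networks a minimal-total-slack certificate is computed: the L1-smallest
#' widening of the (selected) bounds that restores feasibility — the same
#' certificate [relax_to_feasible()] applies.
#'
#' @param net a `MetabolicNetwork`.
#' @param slack_reactions reaction ids whose bounds the slack certificate may
#'   widen (default: all reactions).
#' @return list with `feasible`, `status`, `total_slack`, and a `slack`
#'   data.frame (reaction, slack_lower, slack_upper) for reactions needing
#'   positive slack; plus `bad_bounds` when status is
#'   `"infeasible_by_bounds"`.
#' @export
check_feasibility <- function(net, slack_reactions = NULL) {
  bad <- infeasible_bounds(net)
  if (length(bad)) {
    return(list(feasible = FALSE, status = "infeasible_by_bounds",
                bad_bounds = bad, total_slack = NA_real_,
                slack = NULL))
  }
  S <- stoich_matrix(net)
  lb <- net$reactions$lb; ub <- net$reactions$ub
  # quick accept: is the all-zero-shifted LP feasible?
  probe <- solve_flux_lp(numeric(ncol(S)), S, lb, ub)
  if (probe$status == "optimal") {
    return(list(feasible = TRUE, status = "feasible", total_slack = 0,
                slack = data.frame(reaction = character(0),
                                   slack_lower = numeric(0),
                                   slack_upper = numeric(0))))
  }
  idx <- if (is.null(slack_reactions)) seq_len(ncol(S))
         else match(slack_reactions, net$reactions$id)
  if (anyNA(idx)) stop("unknown reaction in slack_reactions")
  res <- solve_slack_lp(S, lb, ub, slack_idx = idx)
  if (res$status != "optimal")
    stop("slack LP failed (base network broken): status ", res$status)
  pos <- which(res$slack_lower > TOL_FEAS | res$slack_upper > TOL_FEAS)
  list(feasible = res$total_slack <= TOL_FEAS,
       status = if (res$total_slack <= TOL_FEAS) "feasible" else "infeasible",
       total_slack = res$total_slack,
       slack = data.frame(reaction = net$reactions$id[pos],
                          slack_lower = res$slack_lower[pos],
                          slack_upper = res$slack_upper[pos]))
}
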