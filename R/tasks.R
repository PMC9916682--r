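# Metabolic-task activity scoring: evaluate a task catalog on each
# phenotype model, normalize into heatmap form, cluster task activities,
# and compute between-phenotype ratios.

split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Evaluate one metabolic task on a model
#'
#' Builds a working copy of the model in the task environment: uptake is
#' closed for every exchange except the task's source metabolites (which
#' keep the model's — possibly contextualized — bounds) and the whitelisted
#' cofactor exchanges (which keep the base-network bounds; oxygen and CO2
#' by default, so a task without `o2_e` in its whitelist is anaerobic).
#' Secretion stays open for all exchanges so lumped pathways can run at
#' steady state. A demand reaction `DM_<met>` is added for each product
#' metabolite, and the task's objective reaction is maximised by FBA.
#'
#' @param model a `MetabolicNetwork` (typically the `$model` of a
#'   `ContextualizedModel`).
#' @param task one row of a task catalog (list or 1-row data.frame with
#'   `task_id`, `sources`, `products`, `objective`, `cofactors`).
#' @param base_net network supplying whitelist bounds; defaults to `model`.
#' @return list with `activity` (optimal flux, 0 if feasible but
#'   unproductive), `status` (`"optimal"`, `"blocked"`, `"infeasible"`),
#'   `task_id`.
#' @export
evaluate_task <- function(model, task, base_net = NULL) {
  task <- as.list(task)
  if (is.null(base_net)) base_net <- model
  sources <- split_ids(task$sources)
  products <- split_ids(task$products)
  cofactors <- split_ids(task$cofactors)
  met_of <- vapply(model$stoich[model$reactions$kind == "exchange"],
                   function(s) names(s), character(1))
  ex_ids <- names(met_of)
  unknown <- setdiff(c(sources, cofactors), c(met_of, model$metabolites$id))
  if (length(unknown))
    stop("task ", task$task_id, " cites unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  if (length(setdiff(products, model$metabolites$id)))
    stop("task ", task$task_id, " cites unknown product metabolite(s)")

  m <- model
  for (ex in ex_ids) {
    met <- met_of[[ex]]
    i <- match(ex, m$reactions$id)
    if (met %in% sources) {
      m$reactions$ub[i] <- max(m$reactions$ub[i], 0)
    } else if (met %in% cofactors) {
      b <- match(ex, base_net$reactions$id)
      m$reactions$lb[i] <- base_net$reactions$lb[b]
      m$reactions$ub[i] <- max(base_net$reactions$ub[b], 0)
    } else {
      m$reactions$lb[i] <- 0
      m$reactions$ub[i] <- max(m$reactions$ub[i], 0, na.rm = TRUE)
      m$reactions$ub[i] <- max(m$reactions$ub[i], m$bound_cap)
    }
  }
  # the task probes capacity, not maintenance: free internal demand
  # reactions (single consumed metabolite, e.g. the maintenance ATP
  # window) from both their floor and their ceiling
  internal <- which(m$reactions$kind != "exchange")
  m$reactions$lb[internal[m$reactions$lb[internal] > 0]] <- 0
  is_demand <- vapply(m$stoich[internal], function(s)
    length(s) == 1L && s < 0, logical(1))
  m$reactions$ub[internal[is_demand]] <-
    pmax(m$reactions$ub[internal[is_demand]], m$bound_cap)
  for (met in products) {
    dm <- paste0("DM_", met)
    if (!dm %in% m$reactions$id) {
      m$reactions <- rbind(
        m$reactions,
        data.frame(id = dm, lb = 0, ub = m$bound_cap, kind = "internal",
                   subsystem = "task demand", stringsAsFactors = FALSE))
      m$stoich[[dm]] <- stats::setNames(-1, met)
    }
  }
  obj <- task$objective
  if (!obj %in% m$reactions$id)
    stop("task ", task$task_id, " objective '", obj,
         "' not resolvable in the model")
  oi <- match(obj, m$reactions$id)
  m$reactions$ub[oi] <- max(m$reactions$ub[oi], m$bound_cap)
  sol <- fba(m, objective_id = obj, direction = "max")
  if (sol$status %in% c("infeasible", "infeasible_by_bounds"))
    return(list(activity = NA_real_, status = "infeasible",
                task_id = task$task_id))
  act <- sol$objective
  list(activity = max(act, 0),
       status = if (act <= TOL_FEAS) "blocked" else "optimal",
       task_id = task$task_id)
}

#' Evaluate a task catalog across phenotype models
#'
#' @param models named list of `MetabolicNetwork` or `ContextualizedModel`
#'   objects (>= 2).
#' @param catalog task catalog data.frame (see
#'   [build_toy_task_catalog()]).
#' @param base_net network supplying cofactor whitelist bounds; defaults to
#'   each contextualized model's own base.
#' @return a `TaskActivityMatrix`: list with `raw` (tasks x models
#'   matrix), `status` (same shape, character), `catalog`.
#' @export
task_activity_matrix <- function(models, catalog, base_net = NULL) {
  stopifnot(length(models) >= 2, nrow(catalog) >= 1)
  if (is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  raw <- matrix(NA_real_, nrow(catalog), length(models),
                dimnames = list(catalog$task_id, names(models)))
  status <- raw
  mode(status) <- "character"
  for (k in seq_along(models)) {
    mk <- models[[k]]
    net <- if (inherits(mk, "ContextualizedModel")) mk$model else mk
    bnet <- base_net %||%
      (if (inherits(mk, "ContextualizedModel")) mk$base else net)
    if (length(infeasible_bounds(net)))
      stop("model ", names(models)[k], " is infeasible by bounds")
    for (i in seq_len(nrow(catalog))) {
      res <- evaluate_task(net, catalog[i, ], base_net = bnet)
      raw[i, k] <- res$activity
      status[i, k] <- res$status
    }
  }
  structure(list(raw = raw, status = status, catalog = catalog),
            class = "TaskActivityMatrix")
}

#' @export
print.TaskActivityMatrix <- function(x, ...) {
  cat("<TaskActivityMatrix> ", nrow(x$raw), " tasks x ", ncol(x$raw),
      " models; blocked: ", sum(x$status == "blocked"),
      ", infeasible: ", sum(x$status == "infeasible"), "\n", sep = "")
  invisible(x)
}

#' Row-normalize task activities into heatmap form
#'
#' Linear min-max map of every row onto `[-1.5, 1.5]` (the attained
#' extrema are exactly -1.5 and 1.5 for non-constant rows). Constant rows
#' map to all zeros and are flagged.
#'
#' @param matrix raw tasks x models matrix (or a `TaskActivityMatrix`).
#' @return list with `normalized` (matrix in `[-1.5, 1.5]`) and
#'   `constant_rows` (row names flagged constant).
#' @export
normalize_activity <- function(matrix) {
  if (inherits(matrix, "TaskActivityMatrix")) matrix <- matrix$raw
  rng <- t(apply(matrix, 1, range, na.rm = TRUE))
  span <- rng[, 2] - rng[, 1]
  const <- span < .Machine$double.eps^0.5
  out <- matrix
  for (i in seq_len(nrow(matrix))) {
    out[i, ] <- if (const[i]) 0
                else (matrix[i, ] - rng[i, 1]) / span[i] * 3 - 1.5
  }
  list(normalized = out, constant_rows = rownames(matrix)[const])
}

#' Cluster task activity rows
#'
#' Complete-linkage Euclidean clustering of the normalized task rows; the
#' reordered matrix is the artifact downstream heatmaps draw.
#'
#' @param normalized_matrix tasks x models matrix in `[-1.5, 1.5]`.
#' @return list with `tree` (`hclust` of the rows), `ordered`
#'   (leaf-ordered matrix).
#' @export
cluster_tasks <- function(normalized_matrix) {
  tree <- stats::hclust(stats::dist(normalized_matrix, method = "euclidean"),
                        method = "complete")
  list(tree = tree,
       ordered = normalized_matrix[tree$order, , drop = FALSE])
}

#' Between-model activity ratio for one task
#'
#' Raw activity of `task_id` in `model_a` divided by that in `model_b`. A
#' zero denominator is reported as infinite with a flag rather than an
#' error.
#'
#' @param matrix a `TaskActivityMatrix` (or its raw matrix).
#' @param task_id task row.
#' @param model_a,model_b column names.
#' @return list with `ratio`, `finite` (FALSE when the denominator is 0).
#' @export
task_ratio <- function(matrix, task_id, model_a, model_b) {
  if (inherits(matrix, "TaskActivityMatrix")) matrix <- matrix$raw
  a <- matrix[task_id, model_a]
  b <- matrix[task_id, model_b]
  if (is.na(a) || is.na(b)) stop("task activity not finite for ", task_id)
  if (b == 0) return(list(ratio = Inf, finite = FALSE))
  list(ratio = a / b, finite = TRUE)
}
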