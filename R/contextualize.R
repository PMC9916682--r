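# Phenotype-specific model contextualization: exchange-flux quartiles from
# baseline sampling, scaled by plasma fold changes, relaxed to feasibility.

#' Quartiles of sampled transport/exchange fluxes
#'
#' Per reaction, the first and third quartiles (Q1, Q3) of its baseline
#' sampled flux distribution, using the linear-interpolation quantile
#' convention (type 7, the default of the major statistics environments;
#' the single convention used repo-wide).
#'
#' @param sample_set a `FluxSampleSet` from the baseline network.
#' @param reaction_ids transport/exchange reaction ids to summarise.
#' @return a `TransportBounds` data.frame with columns `reaction`, `q1`,
#'   `q3`.
#' @export
transport_quartiles <- function(sample_set, reaction_ids) {
  stopifnot(inherits(sample_set, "FluxSampleSet"))
  absent <- setdiff(reaction_ids, colnames(sample_set$samples))
  if (length(absent))
    stop("reaction(s) absent from samples: ", paste(absent, collapse = ", "))
  q <- t(apply(sample_set$samples[, reaction_ids, drop = FALSE], 2,
               stats::quantile, probs = c(0.25, 0.75), type = 7,
               names = FALSE))
  out <- data.frame(reaction = reaction_ids, q1 = q[, 1], q3 = q[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("TransportBounds", "data.frame")
  out
}

#' Mean concentration fold changes, phenotype over healthy
#'
#' `FC = mean(phenotype concentrations) / mean(healthy concentrations)` per
#' metabolite, computed on raw (unscaled, post-imputation) concentrations —
#' a ratio of means is only meaningful before log/Pareto normalization.
#' Metabolites without an entry in the metabolite-to-exchange mapping are
#' reported as unmapped, never silently dropped.
#'
#' @param phenotype_matrix raw imputed concentrations of the phenotype's
#'   patients (samples x metabolites).
#' @param healthy_matrix raw imputed concentrations of the healthy
#'   controls, same metabolite columns.
#' @param mapping data.frame with columns `metabolite_id`, `reaction_id`
#'   (see [toy_exchange_mapping()]).
#' @return a `FoldChangeVector`: list with `fc` (named numeric, mapped
#'   metabolites), `reactions` (named character, metabolite -> reaction),
#'   `unmapped` (metabolites without a transport mapping).
#' @export
compute_fold_changes <- function(phenotype_matrix, healthy_matrix, mapping) {
  shared <- intersect(colnames(phenotype_matrix), colnames(healthy_matrix))
  if (!setequal(colnames(phenotype_matrix), colnames(healthy_matrix)))
    stop("phenotype and healthy matrices must share metabolite columns")
  hm <- colMeans(healthy_matrix[, shared, drop = FALSE])
  bad <- shared[hm <= 0]
  if (length(bad))
    stop("healthy mean <= 0 for: ", paste(bad, collapse = ", "))
  fc_all <- colMeans(phenotype_matrix[, shared, drop = FALSE]) / hm
  mapped <- mapping$metabolite_id[mapping$metabolite_id %in% shared]
  structure(list(
    fc = fc_all[mapped],
    reactions = stats::setNames(
      mapping$reaction_id[match(mapped, mapping$metabolite_id)], mapped),
    unmapped = setdiff(shared, mapped),
    fc_all = fc_all
  ), class = "FoldChangeVector")
}

#' @export
print.FoldChangeVector <- function(x, ...) {
  cat("<FoldChangeVector> ", length(x$fc), " mapped metabolites, ",
      length(x$unmapped), " unmapped\n", sep = "")
  invisible(x)
}

#' Scale quartile bounds by fold changes
#'
#' Per mapped reaction the candidate bounds are `(FC * Q1, FC * Q3)`; the
#' final `(lb, ub)` is the (min, max) of the pair so the ordering survives
#' any sign pattern. Reactions present in `bounds` but without a fold
#' change keep their baseline quartile bounds.
#'
#' @param bounds a `TransportBounds`.
#' @param fc a `FoldChangeVector` whose reactions are all present in
#'   `bounds`.
#' @return data.frame with columns `reaction`, `lb`, `ub`, `fc`.
#' @export
apply_fold_changes <- function(bounds, fc) {
  stopifnot(inherits(bounds, "TransportBounds"),
            inherits(fc, "FoldChangeVector"))
  missing_rxn <- setdiff(fc$reactions, bounds$reaction)
  if (length(missing_rxn))
    stop("fold-change reaction(s) not in bounds: ",
         paste(missing_rxn, collapse = ", "))
  f <- rep(1, nrow(bounds))
  names(f) <- bounds$reaction
  f[fc$reactions] <- unname(fc$fc)
  cand1 <- f * bounds$q1
  cand2 <- f * bounds$q3
  data.frame(reaction = bounds$reaction,
             lb = pmin(cand1, cand2),
             ub = pmax(cand1, cand2),
             fc = unname(f),
             stringsAsFactors = FALSE)
}

#' Constrain a network and relax minimally to feasibility
#'
#' Applies the fold-change-scaled bounds to the network. If the constrained
#' model is feasible it is returned with an empty relaxation log; otherwise
#' an L1-minimal slack LP (slack allowed only on the constrained bounds —
#' internal reaction bounds are never relaxed) determines the smallest
#' widening that restores feasibility, and exactly the reactions with
#' positive slack are widened and logged.
#'
#' @param net the base `MetabolicNetwork`.
#' @param constrained_bounds data.frame from [apply_fold_changes()].
#' @return a `ContextualizedModel`: list with `model` (the constrained,
#'   possibly relaxed network), `base` (the base network), `applied_bounds`
#'   (the requested bounds), `relaxation_log` (data.frame reaction,
#'   bound, original, relaxed, slack).
#' @export
relax_to_feasible <- function(net, constrained_bounds) {
  cb <- constrained_bounds
  m <- net
  for (i in seq_len(nrow(cb)))
    m <- set_bounds(m, cb$reaction[i], lb = cb$lb[i], ub = cb$ub[i])
  empty_log <- data.frame(reaction = character(0), bound = character(0),
                          original = numeric(0), relaxed = numeric(0),
                          slack = numeric(0), stringsAsFactors = FALSE)
  feas <- check_feasibility(m, slack_reactions = cb$reaction)
  if (feas$status == "infeasible_by_bounds")
    stop("constrained bounds inconsistent for: ",
         paste(feas$bad_bounds, collapse = ", "))
  if (feas$feasible) {
    return(structure(list(model = m, base = net, applied_bounds = cb,
                          relaxation_log = empty_log),
                     class = "ContextualizedModel"))
  }
  sl <- feas$slack
  logs <- list()
  for (i in seq_len(nrow(sl))) {
    r <- sl$reaction[i]
    idx <- match(r, m$reactions$id)
    if (sl$slack_lower[i] > TOL_FEAS) {
      orig <- m$reactions$lb[idx]
      m$reactions$lb[idx] <- orig - sl$slack_lower[i]
      logs[[length(logs) + 1L]] <- data.frame(
        reaction = r, bound = "lb", original = orig,
        relaxed = m$reactions$lb[idx], slack = sl$slack_lower[i],
        stringsAsFactors = FALSE)
    }
    if (sl$slack_upper[i] > TOL_FEAS) {
      orig <- m$reactions$ub[idx]
      m$reactions$ub[idx] <- orig + sl$slack_upper[i]
      logs[[length(logs) + 1L]] <- data.frame(
        reaction = r, bound = "ub", original = orig,
        relaxed = m$reactions$ub[idx], slack = sl$slack_upper[i],
        stringsAsFactors = FALSE)
    }
  }
  post <- check_feasibility(m)
  if (!post$feasible)
    stop("relaxation failed to restore feasibility (base network broken)")
  structure(list(model = m, base = net, applied_bounds = cb,
                 relaxation_log = if (length(logs)) do.call(rbind, logs)
                                  else empty_log),
            class = "ContextualizedModel")
}

#' @export
print.ContextualizedModel <- function(x, ...) {
  cat("<ContextualizedModel> ", nrow(x$applied_bounds),
      " constrained reactions, ", nrow(x$relaxation_log),
      " relaxed bound(s)\n", sep = "")
  invisible(x)
}

#' Contextualize a network for one phenotype
#'
#' Convenience wrapper running the full §-by-§ recipe: quartiles of the
#' baseline sampled exchange fluxes, fold changes of the phenotype's raw
#' plasma concentrations over healthy, quartile scaling, and minimal
#' relaxation to feasibility.
#'
#' @param net the base `MetabolicNetwork`.
#' @param sample_set baseline `FluxSampleSet` of `net`.
#' @param phenotype_matrix,healthy_matrix raw imputed concentration
#'   matrices (see [compute_fold_changes()]).
#' @param mapping metabolite-to-exchange mapping data.frame.
#' @return a `ContextualizedModel`.
#' @export
contextualize_phenotype <- function(net, sample_set, phenotype_matrix,
                                    healthy_matrix, mapping) {
  fc <- compute_fold_changes(phenotype_matrix, healthy_matrix, mapping)
  tb <- transport_quartiles(sample_set, unname(fc$reactions))
  cb <- apply_fold_changes(tb, fc)
  relax_to_feasible(net, cb)
}

#' Contextualize directly from fold-change values
#'
#' Variant of [contextualize_phenotype()] taking explicit fold changes
#' (e.g. the two-phenotype direction-recovery design of
#' [two_phenotype_fold_changes()]) instead of concentration matrices.
#'
#' @param net the base `MetabolicNetwork`.
#' @param sample_set baseline `FluxSampleSet` of `net`.
#' @param fc_values named numeric vector of fold changes keyed by
#'   metabolite id.
#' @param mapping metabolite-to-exchange mapping data.frame.
#' @return a `ContextualizedModel`.
#' @export
contextualize_from_fc <- function(net, sample_set, fc_values, mapping) {
  mapped <- intersect(names(fc_values), mapping$metabolite_id)
  fc <- structure(list(
    fc = fc_values[mapped],
    reactions = stats::setNames(
      mapping$reaction_id[match(mapped, mapping$metabolite_id)], mapped),
    unmapped = setdiff(names(fc_values), mapped),
    fc_all = fc_values
  ), class = "FoldChangeVector")
  if (any(fc$fc <= 0)) stop("fold changes must be positive")
  tb <- transport_quartiles(sample_set, unname(fc$reactions))
  cb <- apply_fold_changes(tb, fc)
  relax_to_feasible(net, cb)
}

#' Serialize a contextualized model
#'
#' Writes the constrained network in the JSON network dialect and the
#' relaxation log as JSON next to it.
#'
#' @param cm a `ContextualizedModel`.
#' @param path output path for the network JSON; the relaxation log goes to
#'   `<path>_relaxation.json`.
#' @return named vector of files written, invisibly.
#' @export
write_contextualized_model <- function(cm, path) {
  write_network(cm$model, path)
  log_path <- sub("\\.json$", "_relaxation.json", path)
  jsonlite::write_json(cm$relaxation_log, log_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(network = path, relaxation = log_path))
}
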