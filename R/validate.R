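# Leave-one-out cross-validation of contextualized models over their
# constrained exchange reactions.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Leave-one-out cross-validation of a contextualized model
#'
#' For each constrained exchange reaction `r`: rebuild the model with `r`'s
#' bounds reset to the base network's, sample the flux polytope, and record
#' the sampled population of `r`'s flux — the model's prediction of the
#' held-out uptake/secretion. Each prediction is compared to `r`'s sampled
#' population in the fully constrained model by Welch's two-sample t-test;
#' p-values are Benjamini-Hochberg adjusted across reactions. Prediction
#' accuracy is summarised as the R-squared of predicted means against the
#' held-out constraint midpoints `(lb + ub) / 2`.
#'
#' A leave-one-out model that turns infeasible is recorded as a failed
#' prediction (NA row), not an error.
#'
#' @param cm a `ContextualizedModel` with >= 2 constrained exchanges.
#' @param n_samples flux samples per model (default 500).
#' @param seed integer seed; each leave-one-out run derives its own
#'   sub-seed deterministically.
#' @return a `ValidationReport`: list with `table` (per-reaction
#'   data.frame: held-out bounds and midpoint, predicted mean/sd, t, p, q,
#'   ok flag) and `summary` (R-squared, fraction with q < 0.05, n_samples,
#'   seed).
#' @export
loo_crossvalidate <- function(cm, n_samples = 500, seed) {
  stopifnot(inherits(cm, "ContextualizedModel"))
  if (missing(seed)) stop("seed is mandatory")
  cb <- cm$applied_bounds
  if (nrow(cb) < 2) stop("need >= 2 constrained exchanges")
  full <- sample_fluxes(cm$model, n_samples, seed = seed)
  base_rxn <- cm$base$reactions
  rows <- vector("list", nrow(cb))
  for (i in seq_len(nrow(cb))) {
    r <- cb$reaction[i]
    bidx <- match(r, base_rxn$id)
    loo_model <- set_bounds(cm$model, r,
                            lb = base_rxn$lb[bidx], ub = base_rxn$ub[bidx])
    mid <- (cb$lb[i] + cb$ub[i]) / 2
    pred <- try(sample_fluxes(loo_model, n_samples, seed = seed + i),
                silent = TRUE)
    if (inherits(pred, "try-error")) {
      rows[[i]] <- data.frame(
        reaction = r, held_lb = cb$lb[i], held_ub = cb$ub[i],
        midpoint = mid, predicted_mean = NA_real_, predicted_sd = NA_real_,
        t = NA_real_, p = NA_real_, ok = FALSE, stringsAsFactors = FALSE)
      next
    }
    x <- pred$samples[, r]
    y <- full$samples[, r]
    tt <- if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
      list(statistic = 0, p.value = if (abs(mean(x) - mean(y)) < 1e-9) 1
                                    else 0)
    } else {
      stats::t.test(x, y)  # Welch, unequal variances
    }
    rows[[i]] <- data.frame(
      reaction = r, held_lb = cb$lb[i], held_ub = cb$ub[i],
      midpoint = mid, predicted_mean = mean(x), predicted_sd = stats::sd(x),
      t = unname(tt$statistic), p = tt$p.value, ok = TRUE,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  ok <- tab$ok & !is.na(tab$p)
  if (any(ok)) tab$q[ok] <- bh_adjust(tab$p[ok])
  pm <- tab$predicted_mean[tab$ok]
  mp <- tab$midpoint[tab$ok]
  ss_tot <- sum((mp - mean(mp))^2)
  r2 <- if (ss_tot > 0) 1 - sum((mp - pm)^2) / ss_tot else NA_real_
  structure(list(
    table = tab,
    summary = list(r_squared = r2,
                   frac_q_below_05 = mean(tab$q[ok] < 0.05),
                   n_reactions = nrow(tab),
                   n_failed = sum(!tab$ok),
                   n_samples = n_samples, seed = seed)
  ), class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("<ValidationReport> ", x$summary$n_reactions,
      " held-out exchanges (", x$summary$n_failed, " failed); R^2 = ",
      format(x$summary$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a validation report
#'
#' Per-reaction table as CSV, summary as JSON.
#'
#' @param report a `ValidationReport`.
#' @param csv_path,json_path output paths.
#' @return invisibly, the paths.
#' @export
write_validation_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$table, csv_path, row.names = FALSE)
  jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
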