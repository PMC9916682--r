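# Clinical statistics of the phenotypes: EoT classification, D-vs-rest
# group tests, Kaplan-Meier survival, and summary tables.

#' Classify endotheliopathy of trauma (EoT)
#'
#' EoT is defined by plasma syndecan-1 >= 40 ng/mL (inclusive threshold).
#' Missing syndecan-1 yields a missing flag.
#'
#' @param syndecan1 numeric vector of syndecan-1 levels (ng/mL, >= 0).
#' @param threshold ng/mL cutoff (default 40).
#' @return logical vector.
#' @export
eot_classify <- function(syndecan1, threshold = 40) {
  stopifnot(all(syndecan1 >= 0, na.rm = TRUE))
  syndecan1 >= threshold
}

#' Phenotype-D-versus-rest group test
#'
#' Nonparametric comparison of phenotype D against all other phenotypes
#' pooled: Kruskal-Wallis for numeric variables, Pearson chi-square for
#' categorical ones (without Yates continuity correction by default; the
#' policy is echoed in the output).
#'
#' @param values the variable (numeric or categorical).
#' @param labels phenotype letter per observation.
#' @param d_label the phenotype contrasted against the pooled rest.
#' @param correct apply Yates continuity correction in the 2x2 chi-square.
#' @return list with `test` (`"kruskal"` or `"chisq"`), `statistic`,
#'   `p_value`, `continuity_correction`.
#' @export
group_tests <- function(values, labels, d_label = "D", correct = FALSE) {
  stopifnot(length(values) == length(labels))
  g <- factor(ifelse(labels == d_label, d_label, "rest"),
              levels = c(d_label, "rest"))
  if (any(table(g) == 0)) stop("empty group in D-vs-rest contrast")
  if (is.numeric(values)) {
    kt <- stats::kruskal.test(values, g)
    list(test = "kruskal", statistic = unname(kt$statistic),
         p_value = kt$p.value, continuity_correction = NA)
  } else {
    tab <- table(g, values)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(test = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value, continuity_correction = correct)
  }
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator with right-censoring at `horizon` days (wraps
#' `survival::survfit`).
#'
#' @param times survival days (>= 0).
#' @param events death indicator (TRUE/1 = died).
#' @param group group label per subject (single group if omitted).
#' @param horizon administrative censoring day (default 30).
#' @return list per group: data.frame with `time`, `n_risk`, `n_event`,
#'   `surv` (step values).
#' @export
km_estimate <- function(times, events, group = NULL, horizon = 30) {
  stopifnot(all(times >= 0), length(times) == length(events))
  events <- as.integer(as.logical(events))
  events[times > horizon] <- 0L
  times <- pmin(times, horizon)
  if (is.null(group)) group <- rep("all", length(times))
  if (any(table(group) == 0)) stop("empty group")
  out <- lapply(split(seq_along(times), group), function(idx) {
    fit <- survival::survfit(
      survival::Surv(times[idx], events[idx]) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv)
  })
  out
}

#' Survival probability at a time point
#'
#' @param km one group's data.frame from [km_estimate()].
#' @param t time point.
#' @return S(t), the last step value at or before `t` (1 before the first
#'   event time).
#' @export
km_surv_at <- function(km, t) {
  s <- km$surv[km$time <= t]
  if (length(s) == 0) 1 else s[length(s)]
}

#' Median and IQR / count and percentage summary per phenotype
#'
#' Numeric variables are summarised as `median [Q1, Q3]` (type-7
#' quantiles, the single convention used repo-wide); logical/categorical
#' variables as `n (%)` per category.
#'
#' @param table per-patient data.frame including a `phenotype` column.
#' @param variables columns to summarise (default: all except ids and
#'   phenotype).
#' @return data.frame: one row per variable (and category), one column per
#'   phenotype, plus the D-vs-rest p-value per variable.
#' @export
summarize_cohort <- function(table, variables = NULL) {
  stopifnot(nrow(table) > 0, "phenotype" %in% names(table))
  if (is.null(variables))
    variables <- setdiff(names(table), c("sample_id", "phenotype"))
  phenos <- sort(unique(table$phenotype))
  rows <- list()
  fmt_num <- function(x) sprintf(
    "%.3g [%.3g, %.3g]", stats::median(x),
    stats::quantile(x, 0.25, type = 7), stats::quantile(x, 0.75, type = 7))
  fmt_cnt <- function(k, n) sprintf("%d (%.1f%%)", k,
                                    if (n > 0) 100 * k / n else 0)
  for (v in variables) {
    x <- table[[v]]
    p <- tryCatch(group_tests(if (is.numeric(x)) x else as.character(x),
                              table$phenotype)$p_value,
                  error = function(e) NA_real_)
    if (is.numeric(x)) {
      cells <- vapply(phenos, function(g)
        fmt_num(x[table$phenotype == g]), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, category = "", t(cells), p_value = p,
        stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      x <- if (is.logical(x)) factor(x, c(FALSE, TRUE), c("no", "yes"))
           else factor(x)
      for (lev in levels(x)) {
        cells <- vapply(phenos, function(g) {
          sel <- table$phenotype == g
          fmt_cnt(sum(x[sel] == lev, na.rm = TRUE), sum(sel))
        }, character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, category = lev, t(cells), p_value = p,
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + length(phenos))] <- phenos
  out
}

#' Reference outcome counts for the emulated four-phenotype trauma cohort
#'
#' The published aggregate counts the synthetic generator is calibrated
#' against: per phenotype, group size and the numbers of deaths within
#' 24 h, 72 h and 30 days, patients transfused within 4 h of admission,
#' and patients with endotheliopathy of trauma (syndecan-1 >= 40 ng/mL).
#' Shipped as a plain-text table under `extdata`.
#'
#' @return data.frame with columns `phenotype`, `n`, `deaths_24h`,
#'   `deaths_72h`, `deaths_30d`, `transfused_4h`, `eot`.
#' @export
phenotype_outcome_counts <- function() {
  utils::read.csv(system.file("extdata", "phenotype_outcome_counts.csv",
                              package = "shinegem"),
                  stringsAsFactors = FALSE)
}

#' Headline rates derived from the reference outcome counts
#'
#' Computed from [phenotype_outcome_counts()]: the share of all <=72-h
#' deaths belonging to phenotype D, and phenotype D's 30-day mortality,
#' 24-h mortality, 4-h transfusion rate and EoT rate (percent).
#'
#' @return named numeric vector of percentages.
#' @export
phenotype_outcome_rates <- function() {
  x <- phenotype_outcome_counts()
  d <- x[x$phenotype == "D", ]
  c(share_72h_deaths_in_D = 100 * d$deaths_72h / sum(x$deaths_72h),
    mortality_30d_D = 100 * d$deaths_30d / d$n,
    mortality_24h_D = 100 * d$deaths_24h / d$n,
    transfused_4h_D = 100 * d$transfused_4h / d$n,
    eot_D = 100 * d$eot / d$n)
}
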