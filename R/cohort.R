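# Synthetic trauma cohort generator.
#
# Emulates the statistical structure the pipeline assumes: 99 trauma
# patients in three injury-severity strata plus 20 healthy controls; a
# 62-metabolite quantified plasma panel with log-normal noise, four latent
# phenotypes expressed as log2 mean shifts on discriminant metabolites
# (succinate shifted highest in phenotype D), one perfectly correlated
# metabolite pair (fumarate generated 1:1 from malate), eight metabolites
# with >30% missingness, four planted multivariate outliers, and
# phenotype-conditional clinical covariates with medians mirroring the
# four-phenotype trauma cohort this package models. Survival uses a
# constant per-phenotype daily death hazard calibrated to the 30-day
# mortality of each phenotype.

#' Default per-phenotype log2 shift matrix
#'
#' Phenotypes x metabolites matrix of log2 mean shifts relative to healthy
#' plasma. Named panel metabolites carry the biology (succinate highest in
#' D, glucose/lactate up in A, glutamine up in B/C, fatty-acid and
#' amino-acid analogs up in D); each phenotype additionally has three
#' generic discriminant metabolites shifted by `discriminant_shift`.
#'
#' @param metabolite_names panel metabolite names.
#' @param discriminant_shift log2 shift of the generic phenotype markers.
#' @return numeric matrix with rownames A-D.
#' @keywords internal
default_shift_matrix <- function(metabolite_names, discriminant_shift = 1.6) {
  sh <- matrix(0, 4, length(metabolite_names),
               dimnames = list(c("A", "B", "C", "D"), metabolite_names))
  set_sh <- function(p, met, val) {
    sh[p, met] <<- val
  }
  d <- discriminant_shift
  set_sh("A", c("glucose", "lactate"), 1.2)
  set_sh("A", c("acetoacetate", "methylglyoxal"), 1.0)
  set_sh("A", c("met_16", "met_17", "met_18"), d)
  set_sh("B", c("glutamine", "oleate"), 1.2)
  set_sh("B", "glutamate", 1.0)
  set_sh("B", c("met_19", "met_20", "met_21"), d)
  set_sh("C", "glutamine", 1.0)
  set_sh("C", "malate", 1.2)
  set_sh("C", c("met_22", "met_23", "met_24"), d)
  set_sh("D", "succinate", 2.5)
  set_sh("D", c("palmitate", "alanine"), 1.2)
  set_sh("D", c("palmitoleate", "urea"), 0.8)
  set_sh("D", "glucose", -0.6)
  set_sh("D", "glutamine", -0.8)
  set_sh("D", c("met_25", "met_26", "met_27"), d)
  # fumarate mirrors malate exactly (generated 1:1 downstream)
  sh[, "fumarate"] <- sh[, "malate"]
  sh
}

default_metabolite_names <- function(n_metabolites = 62) {
  named <- c("glucose", "lactate", "succinate", "malate", "fumarate",
             "palmitate", "oleate", "alanine", "glutamine", "acetoacetate",
             "palmitoleate", "methylglyoxal", "bicarbonate", "glutamate",
             "urea")
  c(named, sprintf("met_%02d", seq(length(named) + 1L, n_metabolites)))
}

#' Cohort specification
#'
#' Collects every tunable of the synthetic cohort generator with defaults
#' matching the study design the pipeline targets: ISS strata of 20/40/39
#' patients, 20 healthy controls, a 62-metabolite panel of which 8 have
#' >30% missingness, phenotype sizes 33/17/24/21 (A/B/C/D) among the 95
#' non-outlier patients, 4 planted outliers, and per-phenotype daily death
#' hazards solving `1 - (1 - h)^30 = p30` for 30-day mortalities of
#' 30.3%/29.4%/16.7%/76.2% (A/B/C/D).
#'
#' @param n_per_iss_stratum patients per ISS stratum (minor/serious/severe).
#' @param n_healthy healthy controls.
#' @param n_metabolites panel size.
#' @param phenotype_sizes named counts for A-D among non-outlier patients.
#' @param sigma_log shared log-normal noise sd (natural log).
#' @param discriminant_shift log2 shift of generic phenotype markers.
#' @param high_missing_metabolites names of metabolites planted with >30%
#'   missingness.
#' @param high_missing_rate_range uniform range the per-metabolite planted
#'   missingness rates are drawn from (must stay above 0.30).
#' @param background_missing_rate per-cell missingness for all other
#'   metabolites (kept below 2% per column).
#' @param n_outliers planted multivariate outliers.
#' @param outlier_sigma displacement in score-standard-deviation units
#'   along the cohort's first two latent components.
#' @param mortality_30d named 30-day mortality per phenotype.
#' @param seed integer seed (mandatory).
#' @return object of class `CohortSpec`.
#' @export
cohort_spec <- function(n_per_iss_stratum = c(20L, 40L, 39L),
                        n_healthy = 20L,
                        n_metabolites = 62L,
                        phenotype_sizes = c(A = 33L, B = 17L, C = 24L,
                                            D = 21L),
                        sigma_log = 0.4,
                        discriminant_shift = 1.6,
                        high_missing_metabolites = sprintf("met_%02d", 55:62),
                        high_missing_rate_range = c(0.35, 0.55),
                        background_missing_rate = 0.005,
                        n_outliers = 4L,
                        outlier_sigma = 6,
                        mortality_30d = c(A = 0.303, B = 0.294, C = 0.167,
                                          D = 0.762),
                        seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_metabolites >= 20,
            all(high_missing_rate_range > 0 & high_missing_rate_range < 1),
            high_missing_rate_range[1] > 0.30,
            all(mortality_30d >= 0 & mortality_30d <= 1),
            sum(phenotype_sizes) + n_outliers == sum(n_per_iss_stratum))
  mets <- default_metabolite_names(n_metabolites)
  stopifnot(all(high_missing_metabolites %in% mets))
  structure(list(
    n_per_iss_stratum = n_per_iss_stratum,
    n_healthy = n_healthy,
    n_metabolites = n_metabolites,
    metabolites = mets,
    phenotype_sizes = phenotype_sizes,
    shift = default_shift_matrix(mets, discriminant_shift),
    sigma_log = sigma_log,
    high_missing_metabolites = high_missing_metabolites,
    high_missing_rate_range = high_missing_rate_range,
    background_missing_rate = background_missing_rate,
    n_outliers = n_outliers,
    outlier_sigma = outlier_sigma,
    daily_hazard = 1 - (1 - mortality_30d)^(1 / 30),
    mortality_30d = mortality_30d,
    seed = as.integer(seed)
  ), class = "CohortSpec")
}

#' Simulate a synthetic trauma + healthy cohort
#'
#' Draws metabolite concentrations as log-normals with phenotype-specific
#' log2 mean shifts, plants the missingness pattern, the 1:1-correlated
#' fumarate/malate pair, and the multivariate outliers, and draws clinical
#' covariates and survival from phenotype-conditional distributions. The
#' same seed reproduces the cohort bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @return a `GeneratedCohort`: list with `concentrations` (samples x
#'   metabolites matrix, `NA` where missing), `samples` (id, type),
#'   `clinical` (per-patient covariate table including phenotype, survival
#'   day and death indicator), `phenotype` (named true labels for
#'   patients), `outliers` (planted outlier sample ids), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n_pat <- sum(spec$n_per_iss_stratum)
  n_all <- n_pat + spec$n_healthy
  mets <- spec$metabolites
  p <- length(mets)
  sd2 <- spec$sigma_log / log(2)  # noise sd on the log2 scale

  pat_ids <- sprintf("P%03d", seq_len(n_pat))
  hv_ids <- sprintf("H%03d", seq_len(spec$n_healthy))

  # phenotype labels: planted sizes among non-outliers; outliers drawn on
  # top of a random phenotype each, then displaced
  pheno_core <- rep(names(spec$phenotype_sizes), spec$phenotype_sizes)
  outlier_pheno <- sample(names(spec$phenotype_sizes), spec$n_outliers,
                          replace = TRUE)
  pheno <- sample(c(pheno_core, outlier_pheno))  # shuffle over patients
  names(pheno) <- pat_ids
  outlier_ids <- sample(pat_ids, spec$n_outliers)

  # baseline log2 abundances per metabolite (arbitrary units; only fold
  # structure is meaningful)
  baseline <- stats::rnorm(p, mean = 5, sd = 1.2)
  names(baseline) <- mets

  L <- matrix(stats::rnorm(n_all * p, sd = sd2), n_all, p,
              dimnames = list(c(pat_ids, hv_ids), mets))
  L <- sweep(L, 2, baseline, `+`)
  L[pat_ids, ] <- L[pat_ids, ] + spec$shift[pheno, , drop = FALSE]

  # planted outliers: displaced outlier_sigma score-standard-deviations
  # along the cohort's first two latent components (the dominant variance
  # directions spanned by the phenotype shifts), so they fall far outside
  # the bulk PCA 1-2 confidence ellipse
  Z <- spec$shift[pheno, , drop = FALSE]
  lat <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  w <- lat$rotation[, 1:2, drop = FALSE]
  score_sd <- sqrt(lat$sdev[1:2]^2 + sd2^2)
  for (id in outlier_ids) {
    sgn <- sample(c(-1, 1), 2, replace = TRUE)
    L[id, ] <- L[id, ] + spec$outlier_sigma *
      as.vector(w %*% (sgn * score_sd))
  }

  # perfect correlate: fumarate generated 1:1 from malate (constant ratio)
  if (all(c("malate", "fumarate") %in% mets))
    L[, "fumarate"] <- L[, "malate"] - 0.3

  conc <- 2^L

  # missingness: planted high-missingness metabolites get a deterministic
  # count above 30%; background metabolites at most 2% of cells
  miss <- matrix(FALSE, n_all, p, dimnames = dimnames(conc))
  for (m in spec$high_missing_metabolites) {
    rate <- stats::runif(1, spec$high_missing_rate_range[1],
                         spec$high_missing_rate_range[2])
    n_miss <- max(ceiling(rate * n_all), floor(0.30 * n_all) + 1L)
    miss[sample(n_all, n_miss), m] <- TRUE
  }
  bg <- setdiff(mets, c(spec$high_missing_metabolites, "malate", "fumarate"))
  cap <- max(0L, floor(0.02 * n_all) - 1L)
  for (m in bg) {
    n_miss <- min(stats::rbinom(1, n_all, spec$background_missing_rate), cap)
    if (n_miss > 0) miss[sample(n_all, n_miss), m] <- TRUE
  }
  conc[miss] <- NA_real_

  clinical <- simulate_clinical(pheno, spec)

  structure(list(
    concentrations = conc,
    samples = data.frame(
      sample_id = c(pat_ids, hv_ids),
      type = rep(c("patient", "healthy"), c(n_pat, spec$n_healthy)),
      stringsAsFactors = FALSE),
    clinical = clinical,
    phenotype = pheno,
    outliers = sort(outlier_ids),
    spec = spec
  ), class = "GeneratedCohort")
}

# Phenotype-conditional clinical covariates. Location parameters follow the
# per-phenotype medians of the cohort being emulated (e.g. syndecan-1
# log-normal location 190 ng/mL in phenotype D); log-normal draws keep the
# skewed biomarkers positive, normal draws serve vitals.
simulate_clinical <- function(pheno, spec) {
  n <- length(pheno)
  loc <- function(vals) unname(vals[pheno])  # vals named A-D
  rln <- function(med, sdlog) stats::rlnorm(n, log(loc(med)), sdlog)
  rno <- function(med, sd) stats::rnorm(n, loc(med), sd)

  iss <- round(rln(c(A = 21, B = 25, C = 25, D = 34), 0.30))
  iss <- pmin(pmax(iss, 1), 75)
  gcs <- round(rno(c(A = 13, B = 12, C = 12, D = 5), 3.5))
  gcs <- pmin(pmax(gcs, 3), 15)
  sbp <- round(rno(c(A = 132, B = 119, C = 111, D = 98), 16))
  hr <- round(rno(c(A = 96, B = 93, C = 101, D = 112), 15))
  base_excess <- round(rno(c(A = -5, B = -3, C = -6, D = -13), 3.5), 1)
  lactate <- round(rln(c(A = 2.3, B = 3.7, C = 3.7, D = 9.8), 0.40), 1)
  glucose <- round(rln(c(A = 134, B = 173, C = 145, D = 229), 0.30))
  epinephrine <- round(rln(c(A = 271, B = 262, C = 230, D = 2240), 1.0))
  norepinephrine <- round(rln(c(A = 1180, B = 1180, C = 741, D = 3460), 1.0))
  syndecan1 <- round(rln(c(A = 34.4, B = 49.5, C = 42.3, D = 190), 0.80), 1)
  stm <- round(rln(c(A = 6.46, B = 6.32, C = 5.93, D = 7.06), 0.30), 2)
  p_tx <- c(A = 0.455, B = 0.471, C = 0.542, D = 0.905)
  transfused_4h <- stats::rbinom(n, 1, unname(p_tx[pheno])) == 1
  rbc_4h <- ifelse(transfused_4h,
                   round(rln(c(A = 2, B = 1.5, C = 2, D = 12), 0.6)), 0)

  hazard <- unname(spec$daily_hazard[pheno])
  death_day <- stats::rgeom(n, hazard) + 1L  # day of death, geometric
  died <- death_day <= 30L
  survival_day <- pmin(death_day, 30L)

  data.frame(
    sample_id = names(pheno),
    phenotype = unname(pheno),
    iss = iss, gcs = gcs, sbp = sbp, heart_rate = hr,
    base_excess = base_excess, lactate = lactate, glucose = glucose,
    epinephrine = epinephrine, norepinephrine = norepinephrine,
    syndecan1 = syndecan1, stm = stm,
    transfused_4h = transfused_4h, rbc_units_4h = rbc_4h,
    eot = eot_classify(syndecan1),
    survival_day = survival_day,
    death = died,
    stringsAsFactors = FALSE)
}

#' @export
print.GeneratedCohort <- function(x, ...) {
  cat("<GeneratedCohort> ", nrow(x$concentrations), " samples x ",
      ncol(x$concentrations), " metabolites (",
      sum(x$samples$type == "patient"), " patients, ",
      sum(x$samples$type == "healthy"), " healthy; ",
      length(x$outliers), " planted outliers; seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' Writes the concentration matrix (samples x metabolites, empty cells for
#' missing values) and the clinical covariate table.
#'
#' @param cohort a `GeneratedCohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conc_path <- file.path(dir, "concentrations.csv")
  clin_path <- file.path(dir, "clinical.csv")
  df <- data.frame(sample_id = rownames(cohort$concentrations),
                   cohort$concentrations, check.names = FALSE)
  utils::write.csv(df, conc_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$clinical, clin_path, row.names = FALSE)
  invisible(c(concentrations = conc_path, clinical = clin_path))
}

#' Read a concentration matrix from CSV
#'
#' @param path CSV whose first column is `sample_id`; empty cells are
#'   missing values.
#' @return samples x metabolites numeric matrix with `NA` for missing.
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Fold-change specification for the two-phenotype contextualization design
#'
#' The direction-recovery experiment contrasts a glycolysis-dominant plasma
#' profile (glucose and lactate elevated, fatty-acid/amino-acid carbon
#' slightly depressed) with a catabolism-dominant profile (fatty-acid,
#' amino-acid and succinate elevated, glucose depressed). Values are mean
#' concentration fold changes (phenotype / healthy) keyed by panel
#' metabolite.
#'
#' @return named list with elements `A_like` and `D_like`, each a named
#'   numeric vector of fold changes.
#' @export
two_phenotype_fold_changes <- function() {
  list(
    A_like = c(glucose = 2.0, lactate = 2.0, succinate = 0.9,
               palmitate = 0.8, alanine = 0.8, glutamine = 1.2,
               acetoacetate = 1.5, palmitoleate = 0.9,
               methylglyoxal = 2.0, bicarbonate = 1.1,
               glutamate = 1.2, urea = 0.8),
    D_like = c(glucose = 0.8, lactate = 1.1, succinate = 2.2,
               palmitate = 2.0, alanine = 2.0, glutamine = 0.7,
               acetoacetate = 0.9, palmitoleate = 1.5,
               methylglyoxal = 0.8, bicarbonate = 1.0,
               glutamate = 0.7, urea = 2.0)
  )
}
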