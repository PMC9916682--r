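# Deterministic toy endothelial-like metabolic network and task catalog.
#
# The toy network is a ~40-reaction lumped carbon/energy/redox map exposing
# the pathways the task catalog probes: glycolysis with its methylglyoxal
# and pentose-phosphate side branches, lactate fermentation, pyruvate
# oxidation and a lumped TCA cycle, an electron-transport reaction burning
# NADH to ATP under an oxygen cap, fatty-acid uptake with beta-oxidation,
# malonyl-CoA-dependent palmitoleate synthesis, acetoacetate formation,
# pooled amino-acid catabolism, an NADPH-generating glutamine route, and a
# thioredoxin reduction cycle. Several lumped steps intentionally drop
# cofactor bookkeeping (e.g. fatty-acid synthesis NADPH) to keep the flux
# space low-dimensional; only relative capacities matter for the analyses.

#' Build the toy endothelial-like network
#'
#' Deterministic: two calls return identical networks. Uptake bounds are
#' negative exchange lower bounds (glucose -10, fatty acid / amino acid /
#' glutamine -5 mmol·gDW^-1·h^-1); the oxygen bound (-100) is deliberately
#' generous so that catabolic task capacities are limited by carbon uptake
#' rather than by respiration. The stored objective is the ATP demand
#' reaction `ATPM`.
#'
#' @return a `MetabolicNetwork` with 31 metabolites and 39 reactions.
#' @export
build_toy_ecgem <- function() {
  mets_e <- c("glc_e", "fa_e", "aa_e", "gln_e", "lac_e", "succ_e", "mgx_e",
              "acac_e", "pmtle_e", "glu_e", "urea_e", "o2_e", "co2_e")
  mets_c <- c("glc", "fa", "aa", "gln", "lac", "pyr", "accoa", "atp",
              "nadh", "nadph", "r5p", "mgx", "succ", "acac", "pmtle",
              "malcoa", "trdox", "trdrd", "glu", "urea", "co2", "o2",
              "tcap")
  metabolites <- data.frame(
    id = c(mets_e, mets_c),
    name = c(mets_e, mets_c),
    compartment = c(rep("e", length(mets_e)), rep("c", length(mets_c))),
    stringsAsFactors = FALSE)

  rxn <- function(id, stoich, lb, ub, subsystem)
    list(id = id, stoich = stoich, lb = lb, ub = ub, subsystem = subsystem)

  defs <- list(
    # exchanges (uptake negative, secretion positive)
    rxn("EX_glc_e",   c(glc_e = -1),   -25, 0,  "exchange"),
    rxn("EX_fa_e",    c(fa_e = -1),    -10, 0,   "exchange"),
    rxn("EX_aa_e",    c(aa_e = -1),    -10, 0,   "exchange"),
    rxn("EX_gln_e",   c(gln_e = -1),   -10, 0,   "exchange"),
    rxn("EX_lac_e",   c(lac_e = -1),    0,  30,  "exchange"),
    rxn("EX_succ_e",  c(succ_e = -1),   0,  15,  "exchange"),
    rxn("EX_mgx_e",   c(mgx_e = -1),    0,  15,  "exchange"),
    rxn("EX_acac_e",  c(acac_e = -1),   0,  15,  "exchange"),
    rxn("EX_pmtle_e", c(pmtle_e = -1),  0,  15,  "exchange"),
    rxn("EX_glu_e",   c(glu_e = -1),    0,  15,  "exchange"),
    rxn("EX_urea_e",  c(urea_e = -1),   0,  20,  "exchange"),
    rxn("EX_o2_e",    c(o2_e = -1),  -100,  0,   "exchange"),
    rxn("EX_co2_e",   c(co2_e = -1),    0, 150,  "exchange"),
    # transports; carbon uptake draws on a shared transporter capacity
    # pool (tcap) so that sampled uptakes concentrate well inside their
    # exchange bounds and are mutually coupled, as in a full-size GEM
    rxn("GLCt",   c(glc_e = -1, tcap = -1, glc = 1), 0, 1000, "transport"),
    rxn("FAt",    c(fa_e = -1, tcap = -1, fa = 1),   0, 1000, "transport"),
    rxn("AAt",    c(aa_e = -1, tcap = -1, aa = 1),   0, 1000, "transport"),
    rxn("GLNt",   c(gln_e = -1, tcap = -1, gln = 1), 0, 1000, "transport"),
    rxn("LACt",   c(lac = -1, lac_e = 1),     0, 1000, "transport"),
    rxn("SUCCt",  c(succ = -1, succ_e = 1),   0, 1000, "transport"),
    rxn("MGXt",   c(mgx = -1, mgx_e = 1),     0, 1000, "transport"),
    rxn("ACACt",  c(acac = -1, acac_e = 1),   0, 1000, "transport"),
    rxn("PMTLEt", c(pmtle = -1, pmtle_e = 1), 0, 1000, "transport"),
    rxn("GLUt",   c(glu = -1, glu_e = 1),     0, 1000, "transport"),
    rxn("UREAt",  c(urea = -1, urea_e = 1),   0, 1000, "transport"),
    rxn("O2t",    c(o2_e = -1, o2 = 1),       0, 1000, "transport"),
    rxn("CO2t",   c(co2 = -1, co2_e = 1),     0, 1000, "transport"),
    # internal (lumped)
    # methylglyoxal is a fixed-fraction nonenzymatic spillover of the
    # triose-phosphate pool: 0.1 of the glucose carbon leaks to mgx
    rxn("GLYC",  c(glc = -1, pyr = 1.8, mgx = 0.2, atp = 2, nadh = 1.8),
        0, 1000, "glycolysis"),
    rxn("PPP",   c(glc = -1, r5p = 1, nadph = 2, co2 = 1), 0, 1000,
        "pentose phosphate"),
    rxn("LDH",   c(pyr = -1, nadh = -1, lac = 1), 0, 1000, "fermentation"),
    rxn("PDH",   c(pyr = -1, accoa = 1, nadh = 1, co2 = 1), 0, 1000,
        "pyruvate oxidation"),
    rxn("TCA",   c(accoa = -1, nadh = 4, atp = 1, co2 = 2), 0, 1000,
        "TCA cycle"),
    rxn("SUCCS", c(accoa = -1, succ = 1, nadh = 1), 0, 1000,
        "TCA cycle exit"),
    rxn("ETC",   c(nadh = -1, o2 = -0.5, atp = 2.5), 0, 1000,
        "oxidative phosphorylation"),
    rxn("BOX",   c(fa = -1, atp = -1, accoa = 3, nadh = 3), 0, 1000,
        "beta-oxidation"),
    rxn("AADEG", c(aa = -1, accoa = 1, nadh = 1, co2 = 1, urea = 1),
        0, 1000, "amino-acid catabolism"),
    rxn("GLNOX", c(gln = -1, nadph = 2, co2 = 1, glu = 1), 0, 1000,
        "NADPH generation"),
    rxn("MCS",   c(accoa = -1, atp = -1, malcoa = 1), 0, 1000,
        "lipogenesis"),
    rxn("FAS",   c(accoa = -1, malcoa = -7, pmtle = 1), 0, 1000,
        "lipogenesis"),
    rxn("ACACS", c(accoa = -2, acac = 1), 0, 1000, "ketogenesis"),
    rxn("TRDR",  c(trdox = -1, nadph = -1, trdrd = 1), 0, 1000,
        "thioredoxin reduction"),
    rxn("TRDOX", c(trdrd = -1, trdox = 1), 0, 1000,
        "antioxidant turnover"),
    # maintenance ATP turnover window: pins total catabolic throughput so
    # sampled boundary fluxes are mutually coupled rather than free to
    # dissipate into CO2 (task evaluation lifts these demand bounds)
    rxn("ATPM",  c(atp = -1), 28, 32, "ATP demand"),
    rxn("R5PD",  c(r5p = -1), 0, 2, "nucleotide synthesis drain"),
    rxn("TCAP",  c(tcap = 20), 0, 1, "transport capacity pool")
  )

  reactions <- data.frame(
    id = vapply(defs, `[[`, character(1), "id"),
    lb = vapply(defs, `[[`, numeric(1), "lb"),
    ub = vapply(defs, `[[`, numeric(1), "ub"),
    subsystem = vapply(defs, `[[`, character(1), "subsystem"),
    stringsAsFactors = FALSE)
  stoich <- stats::setNames(lapply(defs, `[[`, "stoich"), reactions$id)

  metabolic_network(
    id = "toy_ecgem",
    metabolites = metabolites,
    reactions = reactions,
    stoich = stoich,
    objective = list(reaction = "ATPM", direction = "max"))
}

#' Fixture manifest for the toy network
#'
#' Fixed structural facts about [build_toy_ecgem()] that tests and documents
#' rely on: metabolite/reaction counts and the anaerobic glycolytic ATP
#' yield (2 ATP per glucose, so the glycolysis-only ATP task optimum equals
#' twice the glucose uptake bound).
#'
#' @return named list.
#' @export
toy_manifest <- function() {
  list(n_metabolites = 36L,
       n_reactions = 44L,
       n_exchanges = 13L,
       glycolytic_atp_yield = 2,
       objective = "ATPM")
}

#' Build the toy metabolic-task catalog
#'
#' Twelve tasks over the toy network, each defined by its allowed source
#' metabolites (extracellular uptakes), product metabolites (given demand
#' reactions at evaluation time), the objective reaction maximised, and the
#' cofactor exchanges left open (oxygen is deliberately absent from the
#' glycolysis-only ATP task, making it anaerobic). The twelve tasks fall
#' into three activity archetypes: glucose-driven (glycolytic), fatty-acid/
#' amino-acid-driven (catabolic), and glutamine-driven (redox).
#'
#' @return data.frame with columns `task_id`, `description`, `sources`,
#'   `products`, `objective`, `cofactors` (semicolon-separated id lists).
#' @export
build_toy_task_catalog <- function() {
  t <- function(id, desc, sources, products, objective, cofactors)
    data.frame(task_id = id, description = desc, sources = sources,
               products = products, objective = objective,
               cofactors = cofactors, stringsAsFactors = FALSE)
  rbind(
    t("atp_glycolysis", "ATP generation from glycolysis (anaerobic)",
      "glc_e", "", "ATPM", "co2_e"),
    t("atp_glucose_total",
      "ATP generation from glucose (glycolysis + TCA + respiration)",
      "glc_e", "", "ATPM", "o2_e;co2_e"),
    t("mgx_synthesis", "Methylglyoxal synthesis from glucose",
      "glc_e", "mgx", "DM_mgx", "o2_e;co2_e"),
    t("lactate_from_glucose", "Lactate synthesis from glucose",
      "glc_e", "lac", "DM_lac", "o2_e;co2_e"),
    t("r5p_synthesis", "Ribose-5-phosphate synthesis from glucose",
      "glc_e", "r5p", "DM_r5p", "o2_e;co2_e"),
    t("acac_synthesis", "Acetoacetate synthesis from glucose",
      "glc_e", "acac", "DM_acac", "o2_e;co2_e"),
    t("pmtle_synthesis",
      "Palmitoleate synthesis from fatty-acid/amino-acid carbon",
      "fa_e;aa_e", "pmtle", "DM_pmtle", "o2_e;co2_e"),
    t("malcoa_synthesis",
      "Malonyl-CoA synthesis from fatty-acid/amino-acid carbon",
      "fa_e;aa_e", "malcoa", "DM_malcoa", "o2_e;co2_e"),
    t("tca_nadh", "TCA-cycle NADH contribution from catabolic carbon",
      "fa_e;aa_e", "", "TCA", "o2_e;co2_e"),
    t("etc_atp", "Electron-transport-chain activity from catabolic carbon",
      "fa_e;aa_e", "", "ETC", "o2_e;co2_e"),
    t("trdr_activity", "Thioredoxin reductase activity",
      "gln_e", "", "TRDR", "o2_e;co2_e"),
    t("nadph_generation", "NADPH generation from glutamine",
      "gln_e", "nadph", "GLNOX", "o2_e;co2_e")
  )
}

#' Default metabolite-to-exchange mapping for the toy network
#'
#' Maps the named metabolites of the synthetic plasma panel to the boundary
#' exchange reactions of the toy network; panel metabolites without a
#' counterpart in the toy network are deliberately absent (the
#' contextualization step reports them as unmapped rather than dropping them
#' silently).
#'
#' @return data.frame with columns `metabolite_id`, `reaction_id`.
#' @export
toy_exchange_mapping <- function() {
  data.frame(
    metabolite_id = c("glucose", "lactate", "succinate", "palmitate",
                      "alanine", "glutamine", "acetoacetate",
                      "palmitoleate", "methylglyoxal", "bicarbonate",
                      "glutamate", "urea"),
    reaction_id = c("EX_glc_e", "EX_lac_e", "EX_succ_e", "EX_fa_e",
                    "EX_aa_e", "EX_gln_e", "EX_acac_e", "EX_pmtle_e",
                    "EX_mgx_e", "EX_co2_e", "EX_glu_e", "EX_urea_e"),
    stringsAsFactors = FALSE)
}

#' Write the task catalog to CSV
#'
#' @param catalog data.frame from [build_toy_task_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_task_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE)
  invisible(path)
}

#' Read a task catalog from CSV
#'
#' @param path CSV with the columns documented in
#'   [build_toy_task_catalog()].
#' @return data.frame.
#' @export
read_task_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  cat[is.na(cat)] <- ""
  cat
}
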