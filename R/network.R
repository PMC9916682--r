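# MetabolicNetwork: the stoichiometric object every downstream stage acts on.

#' Construct a metabolic network
#'
#' Builds the constraint-based network object used throughout the package: a
#' metabolite table, a reaction table with flux bounds in mmol·gDW^-1·h^-1,
#' per-reaction stoichiometry, and an objective. The sign convention is the
#' standard one for constraint-based models: exchange reactions are written as
#' `met_e ->`, so uptake is a negative exchange flux and secretion positive.
#'
#' Reaction kinds (`exchange`, `transport`, `internal`) are taken from the
#' `kind` argument when supplied and otherwise inferred: a reaction touching
#' exactly one metabolite, located in the boundary compartment, is an
#' exchange; a reaction spanning two or more compartments is a transport;
#' everything else is internal.
#'
#' Infinite bounds are clamped to `+/- bound_cap` (default 1000, the
#' conventional cap in constraint-based models); clamped reactions are
#' recorded so the LP layer can flag optima that escape to an artificial cap
#' as unbounded.
#'
#' @param id character scalar naming the network.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub` and optionally
#'   `kind`, `subsystem`.
#' @param stoich named list (one element per reaction id) of named numeric
#'   vectors mapping metabolite id to stoichiometric coefficient.
#' @param objective list with elements `reaction` (a reaction id) and
#'   `direction` (`"max"` or `"min"`).
#' @param boundary_compartment compartment id treated as extracellular
#'   boundary (default `"e"`).
#' @param bound_cap finite cap substituted for infinite bounds.
#' @return an object of class `MetabolicNetwork`.
#' @export
metabolic_network <- function(id, metabolites, reactions, stoich,
                              objective = NULL,
                              boundary_compartment = "e",
                              bound_cap = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)),
            all(c("id", "lb", "ub") %in% names(reactions)))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids")
  if (!setequal(names(stoich), reactions$id))
    stop("stoichiometry list must have one entry per reaction id")
  stoich <- stoich[reactions$id]
  cited <- unique(unlist(lapply(stoich, names)))
  unknown <- setdiff(cited, metabolites$id)
  if (length(unknown))
    stop("stoichiometry references undeclared metabolites: ",
         paste(unknown, collapse = ", "))

  clamped <- reactions$id[is.infinite(reactions$lb) | is.infinite(reactions$ub)]
  reactions$lb <- pmax(reactions$lb, -bound_cap)
  reactions$ub <- pmin(reactions$ub, bound_cap)

  comp <- stats::setNames(metabolites$compartment, metabolites$id)
  if (is.null(reactions$kind) || all(is.na(reactions$kind))) {
    reactions$kind <- vapply(stoich, function(s) {
      mets <- names(s)
      if (length(mets) == 1L && comp[[mets]] == boundary_compartment)
        return("exchange")
      if (length(unique(comp[mets])) > 1L) return("transport")
      "internal"
    }, character(1))
  }
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_

  net <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoich = stoich,
    objective = objective,
    boundary_compartment = boundary_compartment,
    bound_cap = bound_cap,
    clamped = clamped
  ), class = "MetabolicNetwork")
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: stoichiometry references only declared
#' metabolites, exchange reactions touch exactly one boundary metabolite, and
#' bound ordering. A network with some `lb > ub` is not an error — it is
#' flagged infeasible-by-bounds (see [check_feasibility()]) — but all other
#' violations stop.
#'
#' @param net a `MetabolicNetwork`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "MetabolicNetwork"))
  comp <- stats::setNames(net$metabolites$compartment, net$metabolites$id)
  ex <- net$reactions$id[net$reactions$kind == "exchange"]
  for (r in ex) {
    s <- net$stoich[[r]]
    if (length(s) != 1L)
      stop("exchange reaction ", r, " must touch exactly one metabolite")
    if (comp[[names(s)]] != net$boundary_compartment)
      stop("exchange reaction ", r, " metabolite not in boundary compartment")
  }
  invisible(net)
}

#' Reactions whose lower bound exceeds the upper bound
#'
#' @param net a `MetabolicNetwork`.
#' @return character vector of offending reaction ids (empty if none).
#' @export
infeasible_bounds <- function(net) {
  net$reactions$id[net$reactions$lb > net$reactions$ub]
}

#' Dense stoichiometric matrix
#'
#' @param net a `MetabolicNetwork`.
#' @return metabolites x reactions numeric matrix with dimnames.
#' @export
stoich_matrix <- function(net) {
  S <- matrix(0, nrow(net$metabolites), nrow(net$reactions),
              dimnames = list(net$metabolites$id, net$reactions$id))
  for (j in seq_along(net$stoich)) {
    s <- net$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Set reaction bounds
#'
#' @param net a `MetabolicNetwork`.
#' @param reaction_id reaction id(s).
#' @param lb,ub replacement bounds (recycled; `NA` leaves a bound untouched).
#' @return the modified network.
#' @export
set_bounds <- function(net, reaction_id, lb = NA, ub = NA) {
  idx <- match(reaction_id, net$reactions$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(reaction_id[is.na(idx)], collapse = ", "))
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  keep <- !is.na(lb); net$reactions$lb[idx[keep]] <- lb[keep]
  keep <- !is.na(ub); net$reactions$ub[idx[keep]] <- ub[keep]
  net
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  kinds <- table(x$reactions$kind)
  cat("<MetabolicNetwork> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      " (", paste(names(kinds), kinds, sep = "=", collapse = ", "), ")\n",
      sep = "")
  if (!is.null(x$objective))
    cat("  objective: ", x$objective$direction, " ", x$objective$reaction,
        "\n", sep = "")
  invisible(x)
}

#' Read a metabolic network from disk
#'
#' Supports two formats: the package's JSON dialect
#' (`{metabolites:[{id,name,compartment}], reactions:[{id, stoich:{met:coef},
#' lb, ub, kind}], objective:{reaction, direction}}`) and SBML Level 3 with
#' `fbc` flux bounds. Exchange/transport kinds are inferred from boundary
#' metabolites when the file does not state them.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @return a `MetabolicNetwork`.
#' @export
load_network <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") read_network_json(path) else read_network_sbml(path)
}

read_network_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rxns <- do.call(rbind, lapply(j$reactions, function(r)
    data.frame(id = r$id, lb = r$lb, ub = r$ub,
               kind = r$kind %||% NA_character_,
               subsystem = r$subsystem %||% NA_character_,
               stringsAsFactors = FALSE)))
  stoich <- stats::setNames(lapply(j$reactions, function(r) {
    s <- unlist(r$stoich)
    stats::setNames(as.numeric(s), names(s))
  }), rxns$id)
  objective <- if (!is.null(j$objective))
    list(reaction = j$objective$reaction,
         direction = j$objective$direction %||% "max")
  metabolic_network(id = j$id %||% basename(path),
                    metabolites = mets, reactions = rxns, stoich = stoich,
                    objective = objective,
                    boundary_compartment = j$boundary_compartment %||% "e")
}

#' Write a metabolic network to the JSON dialect
#'
#' @param net a `MetabolicNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  j <- list(
    id = net$id,
    boundary_compartment = net$boundary_compartment,
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i)
      as.list(net$metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
      r <- net$reactions[i, ]
      list(id = r$id, stoich = as.list(net$stoich[[r$id]]),
           lb = r$lb, ub = r$ub, kind = r$kind)
    }),
    objective = net$objective
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Minimal SBML L3 reader: species, reactions with speciesReference
# stoichiometry, fbc:listOfFluxBounds or fbc bound attributes resolved via
# listOfParameters. Boundary species (boundaryCondition or compartment "e")
# define exchanges by inference.
read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing"))
    model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  sp <- xml2::xml_find_all(model, ".//*[local-name()='species']")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(model, ".//*[local-name()='parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  ids <- xml2::xml_attr(rx, "id")
  stoich <- vector("list", length(rx))
  lb <- numeric(length(rx)); ub <- numeric(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    reac <- xml2::xml_find_all(r,
      ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(r,
      ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    co <- function(nodes, sign) {
      if (!length(nodes)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(nodes, "species"))
    }
    s <- c(co(reac, -1), co(prod, 1))
    # merge duplicated species
    stoich[[i]] <- vapply(split(s, names(s)), sum, numeric(1))
    lbref <- xml2::xml_attr(r, "lowerFluxBound")
    ubref <- xml2::xml_attr(r, "upperFluxBound")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb[i] <- if (!is.na(lbref) && lbref %in% names(parval)) parval[[lbref]]
             else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubref) && ubref %in% names(parval)) parval[[ubref]]
             else 1000
  }
  obj_node <- xml2::xml_find_first(model,
    ".//*[local-name()='fluxObjective']")
  objective <- NULL
  if (!inherits(obj_node, "xml_missing")) {
    objective <- list(
      reaction = xml2::xml_attr(obj_node, "reaction"),
      direction = "max")
  }
  metabolic_network(
    id = xml2::xml_attr(model, "id") %||% basename(path),
    metabolites = mets,
    reactions = data.frame(id = ids, lb = lb, ub = ub,
                           stringsAsFactors = FALSE),
    stoich = stats::setNames(stoich, ids),
    objective = objective)
}
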