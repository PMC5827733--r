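#' Construct a compartmentalized metabolic network
#'
#' The central container of the package: a stoichiometric model of an
#' organ's metabolism. Reactions carry flux bounds (in
#' \eqn{\mu}mol liver\eqn{^{-1}} min\eqn{^{-1}}), an optional gene-protein-
#' reaction (GPR) boolean rule, an optional pathway-cluster label, and a
#' role, one of `"intracellular"`, `"exchange"`, `"xenobiotic"` or
#' `"biomass"`. Exchange reactions touch exactly one metabolite, located in
#' an extracellular compartment; by internal convention a *positive*
#' exchange flux secretes the metabolite out of the system and a *negative*
#' flux takes it up (reporting layers convert to the organ-centric
#' uptake-positive convention).
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`.
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoichiometry` (named numeric, metabolite id -> signed coefficient),
#'   `lower_bound`, `upper_bound`, and optionally `name`, `gpr`,
#'   `pathway_cluster`, `role`. Missing bounds default to +-1000; a missing
#'   role is inferred (single extracellular metabolite -> exchange, id
#'   matching "biomass" -> biomass, otherwise intracellular).
#' @param compartments named character vector mapping compartment id to a
#'   human-readable name (e.g. `c(c = "cytosol")`). May be `NULL`, in which
#'   case the set is collected from the metabolites.
#' @param id network identifier string.
#' @param extracellular character vector of compartment ids regarded as
#'   extracellular/interstitial. If `NULL`, compartments whose id or name
#'   matches `e`, `extracellular` or `interstitial` are used.
#' @param validate run [validate_network()] on the result (default `TRUE`).
#' @return An object of class `metabolic_network`.
#' @seealso [load_network()], [stoichiometric_matrix()], [classify_exchanges()]
#' @export
metabolic_network <- function(metabolites, reactions, compartments = NULL,
                              id = "network", extracellular = NULL,
                              validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!all(c("id", "compartment") %in% names(metabolites)))
    dmoma_stop("dmoma_validation_error",
               "metabolites need at least columns 'id' and 'compartment'")
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  metabolites <- metabolites[, c("id", "name", "compartment")]

  if (is.null(compartments)) {
    ids <- unique(metabolites$compartment)
    compartments <- stats::setNames(ids, ids)
  }
  if (is.null(names(compartments)))
    compartments <- stats::setNames(as.character(compartments),
                                    as.character(compartments))

  if (is.null(extracellular)) {
    hit <- grepl("^(e|extracellular|interstitial)$",
                 names(compartments), ignore.case = TRUE) |
           grepl("^(extracellular|interstitial)", unname(compartments),
                 ignore.case = TRUE)
    extracellular <- names(compartments)[hit]
  }

  reactions <- lapply(reactions, normalize_reaction,
                      metabolites = metabolites,
                      extracellular = extracellular)
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")

  net <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         compartments = compartments, extracellular = extracellular),
    class = "metabolic_network")
  if (validate) validate_network(net)
  net
}

normalize_reaction <- function(rxn, metabolites, extracellular) {
  if (is.null(rxn$id))
    dmoma_stop("dmoma_validation_error", "reaction without an 'id' field")
  rxn$name <- rxn$name %||% rxn$id
  st <- unlist(rxn$stoichiometry)
  rxn$stoichiometry <- stats::setNames(as.numeric(st), names(st))
  rxn$lower_bound <- as.numeric(rxn$lower_bound %||% -1000)
  rxn$upper_bound <- as.numeric(rxn$upper_bound %||% 1000)
  rxn$gpr <- as.character(rxn$gpr %||% "")
  rxn$pathway_cluster <- as.character(rxn$pathway_cluster %||% "")
  if (is.null(rxn$role) || !nzchar(rxn$role)) {
    comp <- metabolites$compartment[match(names(rxn$stoichiometry),
                                          metabolites$id)]
    if (length(rxn$stoichiometry) == 1L && !is.na(comp[1]) &&
        comp[1] %in% extracellular) {
      rxn$role <- "exchange"
    } else if (grepl("biomass", rxn$id, ignore.case = TRUE)) {
      rxn$role <- "biomass"
    } else {
      rxn$role <- "intracellular"
    }
  }
  rxn[c("id", "name", "stoichiometry", "lower_bound", "upper_bound",
        "gpr", "pathway_cluster", "role")]
}

#' Validate the structural invariants of a metabolic network
#'
#' Checks: unique metabolite and reaction ids; non-empty reaction list and
#' stoichiometries; every referenced metabolite exists; compartments of all
#' metabolites are declared; `lower_bound <= upper_bound`; exchange
#' reactions touch exactly one extracellular metabolite; known roles.
#' Non-fatal oddities (metabolites in no reaction, absence of any
#' extracellular compartment) raise warnings.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly. Errors have condition class
#'   `dmoma_validation_error`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  m <- net$metabolites
  if (nrow(m) == 0L)
    dmoma_stop("dmoma_validation_error", "network has no metabolites")
  if (anyDuplicated(m$id))
    dmoma_stop("dmoma_validation_error", paste0(
      "duplicate metabolite ids: ",
      paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  if (length(net$reactions) == 0L)
    dmoma_stop("dmoma_validation_error", "network has no reactions")
  rids <- vapply(net$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    dmoma_stop("dmoma_validation_error", paste0(
      "duplicate reaction ids: ",
      paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  bad_comp <- setdiff(unique(m$compartment), names(net$compartments))
  if (length(bad_comp))
    dmoma_stop("dmoma_validation_error", paste0(
      "undeclared compartments: ", paste(bad_comp, collapse = ", ")))

  roles <- c("intracellular", "exchange", "xenobiotic", "biomass")
  for (rxn in net$reactions) {
    if (length(rxn$stoichiometry) == 0L)
      dmoma_stop("dmoma_validation_error",
                 paste0("reaction '", rxn$id, "' has empty stoichiometry"))
    missing <- setdiff(names(rxn$stoichiometry), m$id)
    if (length(missing))
      dmoma_stop("dmoma_validation_error", paste0(
        "reaction '", rxn$id, "' references unknown metabolites: ",
        paste(missing, collapse = ", ")))
    if (rxn$lower_bound > rxn$upper_bound)
      dmoma_stop("dmoma_validation_error", paste0(
        "reaction '", rxn$id, "' has lower_bound > upper_bound"))
    if (!rxn$role %in% roles)
      dmoma_stop("dmoma_validation_error", paste0(
        "reaction '", rxn$id, "' has unknown role '", rxn$role, "'"))
    if (rxn$role == "exchange") {
      comp <- m$compartment[match(names(rxn$stoichiometry), m$id)]
      if (length(rxn$stoichiometry) != 1L ||
          !all(comp %in% net$extracellular))
        dmoma_stop("dmoma_validation_error", paste0(
          "exchange reaction '", rxn$id,
          "' must touch exactly one extracellular metabolite"))
    }
  }

  used <- unique(unlist(lapply(net$reactions,
                               function(r) names(r$stoichiometry))))
  orphans <- setdiff(m$id, used)
  if (length(orphans))
    dmoma_warn(paste0("metabolites not used by any reaction: ",
                      paste(orphans, collapse = ", ")))
  if (length(net$extracellular) == 0L)
    dmoma_warn("network declares no extracellular compartment; no exchange reactions possible")
  invisible(net)
}

#' Assemble the stoichiometric matrix S
#'
#' @param net a validated `metabolic_network`.
#' @return A dense numeric matrix of dimension m metabolites x r reactions,
#'   rows ordered as `net$metabolites$id`, columns as the reaction list;
#'   entries are the signed stoichiometric coefficients.
#' @export
stoichiometric_matrix <- function(net) {
  mids <- net$metabolites$id
  rids <- reaction_ids(net)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (rxn in net$reactions)
    S[names(rxn$stoichiometry), rxn$id] <- rxn$stoichiometry
  S
}

#' Reaction ids of a network
#' @param net a `metabolic_network`.
#' @return character vector in the network's reaction order.
#' @export
reaction_ids <- function(net) {
  vapply(net$reactions, `[[`, character(1), "id", USE.NAMES = FALSE)
}

#' Reaction roles, bounds and cluster labels as vectors
#' @param net a `metabolic_network`.
#' @return named character (or numeric) vector along the reaction order.
#' @export
reaction_roles <- function(net) {
  vapply(net$reactions, `[[`, character(1), "role")
}

#' @rdname reaction_roles
#' @export
lower_bounds <- function(net) {
  vapply(net$reactions, `[[`, numeric(1), "lower_bound")
}

#' @rdname reaction_roles
#' @export
upper_bounds <- function(net) {
  vapply(net$reactions, `[[`, numeric(1), "upper_bound")
}

#' @rdname reaction_roles
#' @export
pathway_clusters <- function(net) {
  vapply(net$reactions, `[[`, character(1), "pathway_cluster")
}

#' Partition reactions into exchange and intracellular classes
#'
#' Exchange reactions are the metabolite utilization reactions crossing the
#' system boundary. For flux-sum purposes every non-exchange reaction --
#' including biomass and xenobiotic reactions -- counts as intracellular.
#'
#' @param net a `metabolic_network`.
#' @return list with character vectors `exchange` and `intracellular`.
#' @export
classify_exchanges <- function(net) {
  roles <- reaction_roles(net)
  ex <- names(roles)[roles == "exchange"]
  if (length(net$extracellular) == 0L && length(ex) == 0L)
    dmoma_warn("no extracellular compartment: exchange set is empty")
  list(exchange = ex, intracellular = setdiff(names(roles), ex))
}

set_bounds <- function(net, id, lb = NULL, ub = NULL) {
  if (!id %in% names(net$reactions))
    dmoma_stop("dmoma_validation_error", paste0("unknown reaction '", id, "'"))
  if (!is.null(lb)) net$reactions[[id]]$lower_bound <- lb
  if (!is.null(ub)) net$reactions[[id]]$upper_bound <- ub
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  roles <- table(reaction_roles(x))
  cat("metabolic_network '", x$id, "': ",
      nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (",
      paste(names(roles), unname(roles), sep = ": ", collapse = ", "),
      "), compartments: ",
      paste(names(x$compartments), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Create a flux distribution over a network
#'
#' A flux distribution is a named numeric vector covering exactly the
#' network's reaction set, with an attribute recording which network it
#' belongs to.
#'
#' @param values named numeric vector, reaction id -> flux.
#' @param net the `metabolic_network` the values refer to.
#' @return named numeric vector of class `flux_distribution`.
#' @export
flux_distribution <- function(values, net) {
  rids <- reaction_ids(net)
  if (!setequal(names(values), rids))
    dmoma_stop("dmoma_validation_error",
               "flux distribution must cover exactly the network's reactions")
  structure(values[rids], class = "flux_distribution", network_id = net$id)
}
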