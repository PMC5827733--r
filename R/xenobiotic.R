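# Xenobiotic reaction templates: phase I-III drug metabolism represented by
# its endogenous cofactor demand only. The drug moiety is mass-balanced on
# the pharmacokinetic side of the coupling, never inside the network.

#' Built-in xenobiotic reaction templates
#'
#' Returns the cofactor-only templates for phase I (oxidation, hydrolysis,
#' reduction), phase II (GSH conjugation, sulfation, acetylation, sugar
#' conjugation, methylation, amino-acid conjugation) and phase III
#' (metabolic integration, ATP transporter, sym-/antiporter) xenobiotic
#' reactions. Each template maps cofactor *roles* (e.g. `accoa`, `coa`) to
#' signed stoichiometric coefficients and restricts the admissible
#' subcellular locations; the acetylation template, for instance, consumes
#' one acetyl-CoA and releases one CoA in the cytosol. Templates are loaded
#' from a JSON file shipped with the package, so a user can supply a
#' modified template set via `path`.
#'
#' The oxidation template consumes O2 only by default; NADPH-dependent
#' (CYP-type) oxidation is available as the opt-in `"nadph"` option.
#'
#' @param path optional path to an alternative template JSON file.
#' @return named list of templates, each with elements `phase`,
#'   `cofactors`, `options`, `locations` (`NULL` = unrestricted).
#' @export
xenobiotic_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "xenobiotic_templates.json",
                                package = "dmoma", mustWork = TRUE)
  doc <- jsonlite::read_json(path)
  doc <- doc[!startsWith(names(doc), "_")]
  lapply(doc, function(t) {
    list(phase = t$phase,
         cofactors = unlist(t$cofactors),
         options = lapply(t$options %||% list(), unlist),
         locations = if (!is.null(t$locations)) unlist(t$locations))
  })
}

#' Instantiate a xenobiotic reaction from a template
#'
#' Maps the template's cofactor roles onto concrete metabolite ids and
#' produces a closed reaction (`bounds [0, 0]`; the coupling loop opens it
#' by pinning the pharmacokinetic rate). The drug itself does not appear in
#' the stoichiometry.
#'
#' @param template template name (see [xenobiotic_templates()]) or a
#'   template object.
#' @param binding named character vector/list, role -> metabolite id; must
#'   cover every role of the template (plus enabled options).
#' @param location compartment *name* (e.g. `"cytosol"`); checked against
#'   the template's allowed locations.
#' @param rid reaction id for the new reaction (must match the rate-table
#'   column that will drive it).
#' @param options character vector of enabled template options, e.g.
#'   `"nadph"` for NADPH-dependent oxidation.
#' @param templates template set to draw from (default: built-in).
#' @return a reaction list suitable for [extend_network()], with
#'   `role = "xenobiotic"` and bounds `[0, 0]`.
#' @export
instantiate_template <- function(template, binding, location, rid,
                                 options = character(),
                                 templates = xenobiotic_templates()) {
  if (is_string(template)) {
    if (!template %in% names(templates))
      dmoma_stop("dmoma_template_error",
                 paste0("unknown xenobiotic template '", template, "'"))
    tname <- template
    template <- templates[[template]]
  } else tname <- "custom"

  if (!is.null(template$locations) &&
      !tolower(location) %in% tolower(template$locations))
    dmoma_stop("dmoma_template_error", paste0(
      "template '", tname, "' is not allowed in location '", location,
      "' (allowed: ", paste(template$locations, collapse = ", "), ")"))

  st <- template$cofactors
  bad_opt <- setdiff(options, names(template$options))
  if (length(bad_opt))
    dmoma_stop("dmoma_template_error", paste0(
      "template '", tname, "' has no option(s): ",
      paste(bad_opt, collapse = ", ")))
  for (opt in options) st <- c(st, template$options[[opt]])

  binding <- unlist(binding)
  unbound <- setdiff(names(st), names(binding))
  if (length(unbound))
    dmoma_stop("dmoma_template_error", paste0(
      "unbound cofactor role(s) for template '", tname, "': ",
      paste(unbound, collapse = ", ")))

  stoich <- stats::setNames(as.numeric(st), unname(binding[names(st)]))
  if (anyDuplicated(names(stoich)))
    stoich <- vapply(split(stoich, names(stoich)), sum, numeric(1))
  list(id = rid, name = paste0(rid, " (", tname, ", ", location, ")"),
       stoichiometry = stoich, lower_bound = 0, upper_bound = 0,
       gpr = "", pathway_cluster = "", role = "xenobiotic")
}

#' Splice xenobiotic reactions into a network
#'
#' Returns a new network extended with the instantiated xenobiotic
#' reactions at their subcellular locations; the input network is left
#' untouched. All added reactions are closed (`[0, 0]`), so the extension
#' is conservative: every feasible flux distribution of the base network
#' stays feasible and every LP optimum is unchanged until rates are pinned.
#'
#' @param net a `metabolic_network`.
#' @param specs list of xenobiotic reaction specs, each a list with
#'   elements `reaction_id`, `template`, `location` (compartment name),
#'   `binding` (role -> metabolite id) and optionally `options`.
#' @return the extended `metabolic_network`.
#' @export
extend_network <- function(net, specs) {
  if (length(specs) == 0L) return(net)
  rid_new <- vapply(specs, function(s) s$reaction_id, character(1))
  if (anyDuplicated(rid_new))
    dmoma_stop("dmoma_validation_error", paste0(
      "duplicate xenobiotic reaction ids in specs: ",
      paste(unique(rid_new[duplicated(rid_new)]), collapse = ", ")))
  clash <- intersect(rid_new, reaction_ids(net))
  if (length(clash))
    dmoma_stop("dmoma_validation_error", paste0(
      "reaction ids already present in the network: ",
      paste(clash, collapse = ", ")))

  comp_name <- function(cid) tolower(unname(net$compartments[cid]))
  new_rxns <- lapply(specs, function(s) {
    rxn <- instantiate_template(s$template, s$binding, s$location,
                                s$reaction_id,
                                options = s$options %||% character())
    # every bound metabolite must exist in the spec'd compartment
    mids <- names(rxn$stoichiometry)
    row <- match(mids, net$metabolites$id)
    if (anyNA(row))
      dmoma_stop("dmoma_validation_error", paste0(
        "spec '", s$reaction_id, "' binds unknown metabolites: ",
        paste(mids[is.na(row)], collapse = ", ")))
    in_loc <- comp_name(net$metabolites$compartment[row]) ==
      tolower(s$location)
    if (!all(in_loc))
      dmoma_stop("dmoma_validation_error", paste0(
        "spec '", s$reaction_id, "' binds metabolites outside '",
        s$location, "': ", paste(mids[!in_loc], collapse = ", ")))
    rxn
  })
  net$reactions <- c(net$reactions,
                     stats::setNames(new_rxns, rid_new))
  validate_network(net)
  net
}

#' Xenobiotic reaction specs for the hepatic isoniazid cascade
#'
#' Builds the cofactor-demand reactions of isoniazid metabolism in the
#' liver: NAT2 acetylation of isoniazid, hydrazine and acetylhydrazine
#' (acetyl-CoA -> CoA, cytosol); amidase hydrolysis of isoniazid and
#' acetylisoniazid (H2O, cytosol); CYP2E1 oxidation of acetylhydrazine
#' (O2 + NADPH -> NADP+, cytosol); glycine conjugation of isonicotinic acid
#' (mitochondria); and NOS2-mediated hydrazine clearance (oxidation,
#' cytosol). The per-reaction stoichiometries are an approximate
#' reconstruction from the generic phase I/II templates; the set is
#' data-driven, so a curated table can replace it.
#'
#' @param net the network the specs will be bound to (used to check the
#'   cofactor metabolites exist).
#' @param cofactors named list of cofactor metabolite ids; defaults match
#'   the toy fixture (`accoa_c`, `coa_c`, `nadph_c`, `nadp_c`, `o2_c`,
#'   `h2o_c`, `gly_m`).
#' @param cyp_nadph should the CYP2E1 oxidation consume NADPH (default
#'   `TRUE`)?
#' @param nos2_nadph should the NOS2 hydrazine clearance consume NADPH
#'   (default `FALSE`, O2 only)?
#' @return list of specs for [extend_network()]; reaction ids `NAT2_INH`,
#'   `NAT2_HZ`, `NAT2_ACHZ`, `AMID_INH`, `AMID_ACINH`, `CYP2E1_ACHZ`,
#'   `GLYAT_INA`, `NOS2_HZ` match the rate columns produced by
#'   [simulate_pbpk()].
#' @export
isoniazid_preset <- function(net,
                             cofactors = list(accoa = "accoa_c",
                                              coa = "coa_c",
                                              nadph = "nadph_c",
                                              nadp = "nadp_c",
                                              o2 = "o2_c",
                                              h2o = "h2o_c",
                                              glycine = "gly_m"),
                             cyp_nadph = TRUE, nos2_nadph = FALSE) {
  need <- c("accoa", "coa", "nadph", "nadp", "o2", "h2o", "glycine")
  missing_role <- setdiff(need, names(cofactors))
  if (length(missing_role))
    dmoma_stop("dmoma_template_error", paste0(
      "cofactor role(s) not configured: ",
      paste(missing_role, collapse = ", ")))
  present <- unlist(cofactors) %in% net$metabolites$id
  if (!all(present))
    dmoma_stop("dmoma_template_error", paste0(
      "network lacks cofactor metabolite(s) for role(s): ",
      paste(names(cofactors)[!present], collapse = ", ")))

  cf <- lapply(cofactors, identity)
  acetyl <- list(accoa = cf$accoa, coa = cf$coa)
  oxid <- list(o2 = cf$o2, nadph = cf$nadph, nadp = cf$nadp)
  list(
    list(reaction_id = "NAT2_INH", template = "acetylation",
         location = "cytosol", binding = acetyl),
    list(reaction_id = "NAT2_HZ", template = "acetylation",
         location = "cytosol", binding = acetyl),
    list(reaction_id = "NAT2_ACHZ", template = "acetylation",
         location = "cytosol", binding = acetyl),
    list(reaction_id = "AMID_INH", template = "hydrolysis",
         location = "cytosol", binding = list(h2o = cf$h2o)),
    list(reaction_id = "AMID_ACINH", template = "hydrolysis",
         location = "cytosol", binding = list(h2o = cf$h2o)),
    list(reaction_id = "CYP2E1_ACHZ", template = "oxidation",
         location = "cytosol", binding = oxid,
         options = if (cyp_nadph) "nadph" else character()),
    list(reaction_id = "GLYAT_INA", template = "aa_conjugation",
         location = "mitochondria", binding = list(aa = cf$glycine)),
    list(reaction_id = "NOS2_HZ", template = "oxidation",
         location = "cytosol", binding = oxid,
         options = if (nos2_nadph) "nadph" else character())
  )
}
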