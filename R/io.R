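#' Read a metabolic network from JSON or SBML
#'
#' The native JSON dialect is the canonical on-disk format (schema below);
#' SBML Level 3 with the `fbc` package (flux bounds, gene-product
#' associations) is supported read-only.
#'
#' JSON schema (all bounds in \eqn{\mu}mol liver\eqn{^{-1}}
#' min\eqn{^{-1}}):
#' \preformatted{
#' {
#'   "id": "toy_liver",
#'   "compartments": {"c": "cytosol", "m": "mitochondria", "e": "extracellular"},
#'   "extracellular": ["e"],
#'   "metabolites": [{"id": "glc_e", "name": "glucose", "compartment": "e"}, ...],
#'   "reactions": [{"id": "EX_glc", "stoichiometry": {"glc_e": -1},
#'                  "lower_bound": 0, "upper_bound": 10,
#'                  "gpr": "", "pathway_cluster": "exchange",
#'                  "role": "exchange"}, ...]
#' }
#' }
#' `lower_bound`/`upper_bound` default to -1000/1000 when absent;
#' reversibility is encoded purely through the bounds. A missing `role` is
#' inferred (single extracellular metabolite -> exchange).
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return a validated [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    dmoma_stop("dmoma_io_error", paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  if (format == "json") load_network_json(path) else load_network_sbml(path)
}

load_network_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) dmoma_stop("dmoma_format_error", paste0(
      "cannot parse '", path, "' as network JSON: ", conditionMessage(e))))
  for (field in c("metabolites", "reactions"))
    if (is.null(doc[[field]]))
      dmoma_stop("dmoma_format_error",
                 paste0("network JSON lacks required field '", field, "'"))
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id) || is.null(m$compartment))
      dmoma_stop("dmoma_format_error",
                 "metabolite entry without 'id' or 'compartment'")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  comp <- if (!is.null(doc$compartments)) unlist(doc$compartments) else NULL
  metabolic_network(
    metabolites = mets, reactions = doc$reactions, compartments = comp,
    id = doc$id %||% tools::file_path_sans_ext(basename(path)),
    extracellular = if (!is.null(doc$extracellular))
      unlist(doc$extracellular))
}

#' Write a metabolic network to the native JSON dialect
#'
#' Round-trips bit-exactly through [load_network()]: stoichiometry, bounds,
#' GPR strings, cluster labels and roles are preserved.
#'
#' @param net a `metabolic_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  doc <- list(
    id = net$id,
    compartments = as.list(net$compartments),
    extracellular = as.list(net$extracellular),
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i)
      as.list(net$metabolites[i, ])),
    reactions = lapply(unname(net$reactions), function(r) {
      r$stoichiometry <- as.list(r$stoichiometry)
      r
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML L3 (+fbc) reader ---------------------------------------------------

load_network_sbml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) dmoma_stop("dmoma_format_error", paste0(
      "cannot parse '", path, "' as XML: ", conditionMessage(e))))
  ns <- xml2::xml_ns(doc)
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(xml2::xml_name(model)))
    dmoma_stop("dmoma_format_error", "SBML file has no <model> element")

  la <- function(node, attr) xml2::xml_attr(node, attr)
  comp_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  comp <- stats::setNames(
    ifelse(is.na(la(comp_nodes, "name")), la(comp_nodes, "id"),
           la(comp_nodes, "name")),
    la(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  # boundary-condition species are outside the balanced system
  boundary <- la(sp_nodes, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = la(sp_nodes, "id"),
    name = ifelse(is.na(la(sp_nodes, "name")), la(sp_nodes, "id"),
                  la(sp_nodes, "name")),
    compartment = la(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)[!boundary, ]

  par_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  params <- stats::setNames(as.numeric(la(par_nodes, "value")),
                            la(par_nodes, "id"))

  rxn_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- lapply(rxn_nodes, function(node) {
    rid <- la(node, "id")
    refs <- function(tag, sign) {
      sr <- xml2::xml_find_all(node, paste0(
        ".//*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
      st <- as.numeric(la(sr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, la(sr, "species"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    st <- st[names(st) %in% mets$id]
    if (anyDuplicated(names(st)))
      st <- tapply(st, names(st), sum)
    bound_of <- function(attr, fallback) {
      ref <- xml2::xml_attr(node, attr, ns = ns)
      if (!is.na(ref) && ref %in% names(params)) params[[ref]] else fallback
    }
    reversible <- la(node, "reversible") %in% c("true", NA)
    lb <- bound_of("fbc:lowerFluxBound", if (reversible) -1000 else 0)
    ub <- bound_of("fbc:upperFluxBound", 1000)
    gpr_node <- xml2::xml_find_first(node,
      ".//*[local-name()='geneProductAssociation']")
    gpr <- if (!is.na(xml2::xml_name(gpr_node)))
      sbml_gpr_string(xml2::xml_children(gpr_node)[[1]]) else ""
    list(id = rid, name = la(node, "name") %||% rid,
         stoichiometry = as.list(st), lower_bound = lb, upper_bound = ub,
         gpr = gpr)
  })

  metabolic_network(
    metabolites = mets, reactions = reactions, compartments = comp,
    id = la(model, "id") %||% tools::file_path_sans_ext(basename(path)))
}

sbml_gpr_string <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    if (is.na(ref)) ref <- xml2::xml_attr(node, "fbc:geneProduct")
    return(ref)
  }
  parts <- vapply(xml2::xml_children(node), sbml_gpr_string, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

# --- tabular inputs ----------------------------------------------------------

#' Read a gene-expression profile
#'
#' Accepts a 2-column TSV/CSV (`gene_id`, `intensity`) or a multi-sample
#' table (`gene_id` plus one numeric column per sample), in which case
#' samples are averaged per gene.
#'
#' @param path file path; the delimiter is sniffed (tab or comma).
#' @return named numeric vector of non-negative intensities.
#' @export
read_expression <- function(path) {
  tab <- read_delim_sniff(path)
  if (ncol(tab) < 2)
    dmoma_stop("dmoma_format_error", "expression table needs >= 2 columns")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals))
    dmoma_stop("dmoma_format_error", "non-numeric expression intensities")
  expr <- rowMeans(vals)
  names(expr) <- as.character(tab[[1]])
  if (any(!is.finite(expr)) || any(expr < 0))
    dmoma_stop("dmoma_format_error",
               "expression intensities must be finite and non-negative")
  if (all(expr == 0))
    dmoma_stop("dmoma_format_error", "all expression intensities are zero")
  expr
}

#' Read an exchange-utilization table
#'
#' CSV with columns `exchange_id`, `lb`, `ub` giving physiological bounds
#' for exchange reactions (internal convention: negative flux = uptake,
#' positive = secretion).
#'
#' @param path file path.
#' @return data frame with columns `exchange_id`, `lb`, `ub`.
#' @export
read_utilization <- function(path) {
  tab <- read_delim_sniff(path)
  need <- c("exchange_id", "lb", "ub")
  if (!all(need %in% names(tab)))
    dmoma_stop("dmoma_format_error",
               "utilization table needs columns exchange_id, lb, ub")
  tab[need]
}

#' Read a pathway-clustering table
#'
#' CSV with columns `reaction_id`, `cluster`; each reaction may belong to
#' at most one cluster.
#'
#' @param path file path.
#' @return named character vector, reaction id -> cluster label.
#' @export
read_pathway_clusters <- function(path) {
  tab <- read_delim_sniff(path)
  if (!all(c("reaction_id", "cluster") %in% names(tab)))
    dmoma_stop("dmoma_format_error",
               "cluster table needs columns reaction_id, cluster")
  if (anyDuplicated(tab$reaction_id))
    dmoma_stop("dmoma_format_error",
               "a reaction may belong to at most one pathway cluster")
  stats::setNames(as.character(tab$cluster), as.character(tab$reaction_id))
}

read_delim_sniff <- function(path) {
  if (!file.exists(path))
    dmoma_stop("dmoma_io_error", paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
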