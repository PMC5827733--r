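# Synthetic toy-liver fixture: a small, hand-designed hepatocyte-like
# network plus matching expression, utilization and pathway-cluster
# tables. The network is a fasted-state caricature: lactate is taken up
# as gluconeogenic substrate, glucose is secreted, a lumped TCA/oxidation
# branch burns acetyl-CoA, an NADPH-producing shunt feeds glutathione
# synthesis, glycine is imported for mitochondrial conjugation, and a
# stoichiometrically disconnected two-step side pathway ("pathway_b")
# provides a perturbation-free control cluster. All cofactor pools needed
# by the isoniazid xenobiotic preset (acetyl-CoA/CoA, NADPH/NADP+, O2,
# H2O, mitochondrial glycine) are present. Uptake bounds are sized so the
# liver can process a full clinical dose's cofactor demand.

toy_core_reactions <- function() {
  rxn <- function(id, st, lb, ub, gpr = "", cluster = "", role = "")
    list(id = id, stoichiometry = st, lower_bound = lb, upper_bound = ub,
         gpr = gpr, pathway_cluster = cluster, role = role)
  list(
    rxn("EX_lac", c(lac_e = -1), -400, 0, cluster = "exchange"),
    rxn("EX_glc", c(glc_e = -1), 0, 400, cluster = "exchange"),
    rxn("EX_o2", c(o2_e = -1), -400, 0, cluster = "exchange"),
    rxn("EX_co2", c(co2_e = -1), 0, 1200, cluster = "exchange"),
    rxn("EX_gly", c(gly_e = -1), -100, 0, cluster = "exchange"),
    rxn("EX_h2o", c(h2o_e = -1), -400, 400, cluster = "exchange"),
    rxn("EX_b1", c(b1_e = -1), -5, 0, cluster = "pathway_b"),
    rxn("EX_b2", c(b2_e = -1), 0, 5, cluster = "pathway_b"),
    rxn("LACt", c(lac_e = -1, lac_c = 1), 0, 400, cluster = "transport"),
    rxn("GLCt", c(glc_c = -1, glc_e = 1), 0, 400, cluster = "transport"),
    rxn("O2t", c(o2_e = -1, o2_c = 1), 0, 400, cluster = "transport"),
    rxn("CO2t", c(co2_c = -1, co2_e = 1), 0, 1200, cluster = "transport"),
    rxn("GLYt", c(gly_e = -1, gly_c = 1), 0, 100, cluster = "transport"),
    rxn("GLYmt", c(gly_c = -1, gly_m = 1), -100, 100,
        cluster = "transport"),
    rxn("H2Ot", c(h2o_e = -1, h2o_c = 1), -400, 400,
        cluster = "transport"),
    rxn("LDH", c(lac_c = -1, pyr_c = 1), 0, 400,
        gpr = "g_ldha or g_ldhb", cluster = "central_carbon"),
    rxn("GNG", c(pyr_c = -2, glc_c = 1), 0, 200,
        gpr = "g_pck1 and g_fbp1", cluster = "central_carbon"),
    rxn("PDH_A", c(pyr_c = -1, coa_c = -1, accoa_c = 1, co2_c = 1),
        0, 400, gpr = "g_pdha1 and g_dlat", cluster = "central_carbon"),
    rxn("PDH_B", c(pyr_c = -1, coa_c = -1, accoa_c = 1, co2_c = 1),
        0, 400, gpr = "g_pdhb_alt", cluster = "central_carbon"),
    rxn("RESP", c(accoa_c = -1, o2_c = -2, coa_c = 1, co2_c = 2,
                  h2o_c = 1),
        0, 400, gpr = "g_cs and g_sdha", cluster = "central_carbon"),
    rxn("NADPHS", c(pyr_c = -1, nadp_c = -2, nadph_c = 2, co2_c = 3),
        0, 400, gpr = "g_g6pd", cluster = "cofactor_metabolism"),
    rxn("GSHS", c(gly_c = -1, nadph_c = -1, gsh_c = 1, nadp_c = 1),
        0, 100, gpr = "g_gss and g_gclc", cluster = "cofactor_metabolism"),
    rxn("PYRmt_f", c(pyr_c = -1, pyr_m = 1), 0, 100,
        gpr = "g_mpc1", cluster = "transport"),
    rxn("PYRmt_r", c(pyr_m = -1, pyr_c = 1), 0, 100,
        gpr = "g_mpc2", cluster = "transport"),
    rxn("BIOMASS", c(pyr_c = -0.5, gly_c = -0.2, accoa_c = -0.2,
                     nadph_c = -0.2, gsh_c = -0.05, coa_c = 0.2,
                     nadp_c = 0.2),
        0, 1000, role = "biomass"),
    rxn("B1t", c(b1_e = -1, b1_c = 1), 0, 5, cluster = "pathway_b"),
    rxn("B12", c(b1_c = -1, b2_c = 1), 0, 5, gpr = "g_bx",
        cluster = "pathway_b"),
    rxn("B2t", c(b2_c = -1, b2_e = 1), 0, 5, cluster = "pathway_b")
  )
}

toy_metabolites <- function() {
  met <- function(id, name, comp) data.frame(id = id, name = name,
                                             compartment = comp)
  do.call(rbind, list(
    met("lac_e", "lactate", "e"), met("lac_c", "lactate", "c"),
    met("pyr_c", "pyruvate", "c"), met("pyr_m", "pyruvate", "m"),
    met("glc_c", "glucose", "c"), met("glc_e", "glucose", "e"),
    met("o2_e", "oxygen", "e"), met("o2_c", "oxygen", "c"),
    met("co2_c", "carbon dioxide", "c"), met("co2_e", "carbon dioxide", "e"),
    met("gly_e", "glycine", "e"), met("gly_c", "glycine", "c"),
    met("gly_m", "glycine", "m"),
    met("accoa_c", "acetyl-CoA", "c"), met("coa_c", "coenzyme A", "c"),
    met("nadph_c", "NADPH", "c"), met("nadp_c", "NADP+", "c"),
    met("gsh_c", "glutathione", "c"),
    met("h2o_e", "water", "e"), met("h2o_c", "water", "c"),
    met("b1_e", "metabolite B1", "e"), met("b1_c", "metabolite B1", "c"),
    met("b2_c", "metabolite B2", "c"), met("b2_e", "metabolite B2", "e")))
}

toy_expression_base <- function() {
  c(g_ldha = 800, g_ldhb = 300, g_pck1 = 700, g_fbp1 = 900,
    g_pdha1 = 850, g_dlat = 750, g_pdhb_alt = 60, g_cs = 950,
    g_sdha = 800, g_g6pd = 700, g_gss = 400, g_gclc = 350,
    g_mpc1 = 880, g_mpc2 = 860, g_bx = 500)
}

#' Generate the synthetic toy-liver fixture
#'
#' Writes a deterministic set of pipeline inputs to `dir`: a network JSON
#' (`network.json`), an expression TSV (`expression.tsv`, base intensities
#' with a seed-dependent +-5% jitter), an exchange-utilization CSV
#' (`utilization.csv`) and a pathway-cluster CSV (`clusters.csv`, which
#' also labels the isoniazid xenobiotic reaction ids under
#' `xenobiotic_metabolism`). The small network has 24 metabolites and 29
#' reactions over cytosol/mitochondria/extracellular with all cofactor
#' pools required by [isoniazid_preset()], a biomass reaction, 8
#' exchanges and 6 pathway clusters; `"medium"` appends five lumped
#' two-step auxiliary pathways (~60 reactions). The network is feasible
#' with biomass >= 1e-4 under the generated utilization table.
#'
#' @param seed integer seed controlling the expression jitter.
#' @param size `"small"` or `"medium"`.
#' @param dir output directory (created if needed).
#' @return list with the four file paths (`network`, `expression`,
#'   `utilization`, `clusters`) and the loaded objects (`net`, `expr`,
#'   `util`, `cluster_map`).
#' @export
generate_toy_fixture <- function(seed = 1, size = c("small", "medium"),
                                 dir = tempfile("fixture")) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  mets <- toy_metabolites()
  rxns <- toy_core_reactions()
  expr <- toy_expression_base()
  if (size == "medium") {
    for (k in 1:5) {
      pre <- paste0("aux", k)
      mets <- rbind(mets,
        data.frame(id = paste0(pre, c("_e", "_c", "p_c", "p_e")),
                   name = paste0("auxiliary metabolite ", k,
                                 c("", "", " product", " product")),
                   compartment = c("e", "c", "c", "e")))
      g <- paste0("g_", pre)
      rxns <- c(rxns, list(
        list(id = paste0("EX_", pre), stoichiometry =
               stats::setNames(-1, paste0(pre, "_e")),
             lower_bound = -20, upper_bound = 0, gpr = "",
             pathway_cluster = "exchange", role = ""),
        list(id = paste0("EX_", pre, "p"), stoichiometry =
               stats::setNames(-1, paste0(pre, "p_e")),
             lower_bound = 0, upper_bound = 20, gpr = "",
             pathway_cluster = "exchange", role = ""),
        list(id = paste0(toupper(pre), "t"), stoichiometry =
               stats::setNames(c(-1, 1), paste0(pre, c("_e", "_c"))),
             lower_bound = 0, upper_bound = 20, gpr = "",
             pathway_cluster = "transport", role = ""),
        list(id = paste0(toupper(pre), "conv"), stoichiometry =
               stats::setNames(c(-1, 1), paste0(pre, c("_c", "p_c"))),
             lower_bound = 0, upper_bound = 20, gpr = g,
             pathway_cluster = paste0("auxiliary_", (k - 1) %% 2 + 1),
             role = ""),
        list(id = paste0(toupper(pre), "pt"), stoichiometry =
               stats::setNames(c(-1, 1), paste0(pre, c("p_c", "p_e"))),
             lower_bound = 0, upper_bound = 20, gpr = "",
             pathway_cluster = "transport", role = "")))
      expr[g] <- 200 + 120 * k
    }
  }

  net <- metabolic_network(
    metabolites = mets, reactions = rxns,
    compartments = c(c = "cytosol", m = "mitochondria",
                     e = "extracellular"),
    id = paste0("toy_liver_", size), extracellular = "e")

  # seed-dependent +-5% multiplicative jitter on the expression profile
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  expr_j <- expr * stats::runif(length(expr), 0.95, 1.05)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  util <- data.frame(
    exchange_id = vapply(rxns, `[[`, character(1), "id"),
    lb = vapply(rxns, `[[`, numeric(1), "lower_bound"),
    ub = vapply(rxns, `[[`, numeric(1), "upper_bound"))
  ex_ids <- reaction_ids(net)[reaction_roles(net) == "exchange"]
  util <- util[util$exchange_id %in% ex_ids, ]

  cluster_map <- pathway_clusters(net)
  cluster_map <- cluster_map[nzchar(cluster_map)]
  cluster_tab <- data.frame(
    reaction_id = c(names(cluster_map), PBPK_REACTIONS),
    cluster = c(unname(cluster_map),
                rep("xenobiotic_metabolism", length(PBPK_REACTIONS))))

  paths <- list(network = file.path(dir, "network.json"),
                expression = file.path(dir, "expression.tsv"),
                utilization = file.path(dir, "utilization.csv"),
                clusters = file.path(dir, "clusters.csv"))
  write_network(net, paths$network)
  utils::write.table(
    data.frame(gene_id = names(expr_j),
               intensity = formatC(expr_j, digits = 10, format = "g")),
    paths$expression, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(util, paths$utilization, row.names = FALSE)
  utils::write.csv(cluster_tab, paths$clusters, row.names = FALSE)

  c(paths, list(net = net,
                expr = stats::setNames(as.numeric(expr_j), names(expr_j)),
                util = util,
                cluster_map = stats::setNames(as.character(cluster_tab$cluster),
                                              cluster_tab$reaction_id)))
}
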