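#!/usr/bin/env Rscript

# Thin command-line front end over the dmoma package.
#
#   Rscript scripts/dmoma.R fixture --seed 1 --size small --dir fixtures/
#   Rscript scripts/dmoma.R run     --config run.yaml [--out DIR]
#   Rscript scripts/dmoma.R compare --a runA --b runB --out cmp.csv
#
# `run` reads a YAML config whose keys mirror dmoma::run_config()
# (network, expression, utilization, clusters, phenotype, dose_umol,
# n_doses, dose_interval, duration, dt, eps, biomass_min, relax, seed);
# command-line flags override config values.

suppressMessages({library(dmoma); library(optparse)})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: dmoma.R <fixture|run|compare> [options]", call. = FALSE)
cmd <- args[1]
rest <- args[-1]

if (cmd == "fixture") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1),
    make_option("--size", default = "small"),
    make_option("--dir", default = "fixture"))), args = rest)
  fx <- generate_toy_fixture(seed = opts$seed, size = opts$size,
                             dir = opts$dir)
  cat("fixture written to", opts$dir, "\n")

} else if (cmd == "run") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character"),
    make_option("--out", type = "character", default = NULL),
    make_option("--phenotype", type = "character", default = NULL),
    make_option("--dt", type = "double", default = NULL),
    make_option("--duration", type = "double", default = NULL))),
    args = rest)
  if (is.null(opts$config)) stop("run needs --config <yaml>", call. = FALSE)
  cfg_list <- yaml::read_yaml(opts$config)
  for (k in c("out_dir", "phenotype", "dt", "duration")) {
    flag <- sub("out_dir", "out", k)
    if (!is.null(opts[[flag]])) cfg_list[[k]] <- opts[[flag]]
  }
  cfg <- do.call(run_config, cfg_list)
  res <- run_pipeline(cfg)
  cat("outputs in", res$out_dir, "\n")

} else if (cmd == "compare") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--a", type = "character"),
    make_option("--b", type = "character"),
    make_option("--out", type = "character", default = "comparison"))),
    args = rest)
  read_run <- function(dir) {
    ps <- utils::read.csv(file.path(dir, "pathway_scores.csv"))
    pools <- utils::read.csv(file.path(dir, "exometabolome_pools.csv"))
    list(pathway_scores = stats::setNames(ps$pathway_score, ps$cluster),
         pools = pools,
         p_rxn = stats::setNames(
           utils::read.csv(file.path(dir, "perturbation_reactions.csv"))$p_rxn,
           utils::read.csv(file.path(dir, "perturbation_reactions.csv"))$reaction_id))
  }
  a <- read_run(opts$a); b <- read_run(opts$b)
  cl <- sort(union(names(a$pathway_scores), names(b$pathway_scores)))
  g0 <- function(v, k) ifelse(k %in% names(v), v[k], 0)
  ps <- data.frame(cluster = cl,
                   ps_a = as.numeric(g0(a$pathway_scores, cl)),
                   ps_b = as.numeric(g0(b$pathway_scores, cl)))
  ps$diff <- ps$ps_b - ps$ps_a
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ps, file.path(opts$out, "pathway_score_diff.csv"),
                   row.names = FALSE)
  pools <- merge(a$pools[c("exchange_id", "pool_change")],
                 b$pools[c("exchange_id", "pool_change")],
                 by = "exchange_id", suffixes = c("_a", "_b"), all = TRUE)
  pools[is.na(pools)] <- 0
  pools$diff <- pools$pool_change_b - pools$pool_change_a
  utils::write.csv(pools, file.path(opts$out, "pool_diff.csv"),
                   row.names = FALSE)
  cat("comparison written to", opts$out, "\n")

} else {
  stop("unknown subcommand '", cmd, "'", call. = FALSE)
}
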