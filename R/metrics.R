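# Perturbation analytics on a dMOMA flux matrix. All time integrals use
# the left-rectangle rule with the coupling step dt -- the QP produces
# piecewise-constant fluxes per step, so the rectangle sum is the exact
# integral of the simulated trajectory; the final grid point closes the
# last interval and contributes no rectangle of its own.

#' Differential fluxes relative to the reference state
#'
#' @param fm a `flux_matrix` from [run_dmoma()].
#' @param ref the `reference_state` (defaults to the one stored in `fm`).
#' @return matrix of the same shape as `fm$fluxes` with
#'   `delta[i, t] = v[i, t] - v_ref[i]`; positive entries are fluxes
#'   increased by the perturbation, negative entries reduced ones.
#' @export
differential_fluxes <- function(fm, ref = fm$ref) {
  if (!setequal(rownames(fm$fluxes), names(ref$v_ref)))
    dmoma_stop("dmoma_validation_error",
               "flux matrix and reference cover different reactions")
  fm$fluxes - as.numeric(ref$v_ref[rownames(fm$fluxes)])
}

step_columns <- function(delta) {
  # columns contributing a rectangle: all but the final grid point
  seq_len(max(1L, ncol(delta) - 1L))
}

#' Integrated perturbations
#'
#' Accumulated absolute flux deviations: per reaction
#' (`which = "rxn"`, umol liver^-1), per exchange reaction
#' (`which = "ex"`, umol of exchanged metabolite), or summed over all
#' xenobiotic driver reactions (`which = "pbpk"`, a single number
#' quantifying the total perturbation injected by the drug's metabolism).
#'
#' @param delta differential flux matrix from [differential_fluxes()].
#' @param dt uniform step width (min).
#' @param which one of `"rxn"`, `"ex"`, `"pbpk"`.
#' @param roles named role vector (from [reaction_roles()]); required for
#'   `"ex"` and `"pbpk"`.
#' @return named numeric vector of integrated perturbations (scalar for
#'   `"pbpk"`).
#' @export
integrate_perturbation <- function(delta, dt, which = c("rxn", "ex", "pbpk"),
                                   roles = NULL) {
  which <- match.arg(which)
  cols <- step_columns(delta)
  p <- rowSums(abs(delta[, cols, drop = FALSE])) * dt
  switch(which,
    rxn = p,
    ex = {
      if (is.null(roles)) dmoma_stop("dmoma_validation_error",
                                     "'roles' needed for which = 'ex'")
      p[names(p) %in% names(roles)[roles == "exchange"]]
    },
    pbpk = {
      if (is.null(roles)) dmoma_stop("dmoma_validation_error",
                                     "'roles' needed for which = 'pbpk'")
      sum(p[names(p) %in% names(roles)[roles == "xenobiotic"]])
    })
}

#' Significantly altered reactions
#'
#' A flux counts as significantly altered when its accumulated
#' perturbation exceeds the time-integrated minimal flux threshold:
#' `P_rxn > eps * t` (strict inequality).
#'
#' @param p_rxn named vector of integrated per-reaction perturbations.
#' @param eps minimal flux threshold (umol liver^-1 min^-1).
#' @param t_total total simulated time (min).
#' @return character vector of significant reaction ids.
#' @export
significance_mask <- function(p_rxn, eps, t_total) {
  stopifnot(eps > 0, t_total > 0)
  names(p_rxn)[p_rxn > eps * t_total]
}

#' Pathway perturbations
#'
#' Per pathway cluster, the sum of integrated perturbations of its
#' *significantly altered* reactions.
#'
#' @param p_rxn named vector of integrated per-reaction perturbations.
#' @param sig character vector of significant reaction ids
#'   (see [significance_mask()]).
#' @param clusters named character vector, reaction id -> cluster label.
#' @return named numeric vector over all cluster labels (clusters without
#'   significant reactions report 0).
#' @export
pathway_perturbation <- function(p_rxn, sig, clusters) {
  labels <- sort(unique(unname(clusters)))
  out <- stats::setNames(numeric(length(labels)), labels)
  keep <- intersect(names(clusters), intersect(names(p_rxn), sig))
  for (rid in keep)
    out[[clusters[[rid]]]] <- out[[clusters[[rid]]]] + p_rxn[[rid]]
  out
}

#' Attenuation curve of a pathway perturbation
#'
#' Cumulative per-step pathway perturbation normalized by the whole-run
#' total: a curve in `[0, 1]`, non-decreasing, ending at 1. A fast-peaked,
#' quickly attenuated perturbation approaches 1 early; a sustained
#' perturbation approaches it late.
#'
#' @param p_mp_series numeric vector of per-step pathway perturbations.
#' @param p_mp_total whole-run pathway perturbation (normally
#'   `sum(p_mp_series)`).
#' @return numeric vector of the same length; `numeric(0)` with a warning
#'   when the total is 0 (the curve is undefined).
#' @export
attenuation_curve <- function(p_mp_series, p_mp_total = sum(p_mp_series)) {
  if (p_mp_total <= 0) {
    dmoma_warn("pathway perturbation total is 0: attenuation undefined")
    return(numeric(0))
  }
  cumsum(p_mp_series) / p_mp_total
}

#' Pathway scores
#'
#' Pathway perturbation normalized to the perturbation injected by the
#' xenobiotic metabolism: `PS = P_MP / P_PBPK`. A score above 1 indicates
#' aggravation of the drug-induced perturbation in that pathway, a score
#' in (0, 1) a partial perturbation, and 0 independence.
#'
#' @param p_mp named per-cluster perturbations (see
#'   [pathway_perturbation()]).
#' @param p_pbpk scalar xenobiotic driver perturbation.
#' @return named numeric vector of scores.
#' @export
pathway_score <- function(p_mp, p_pbpk) {
  if (p_pbpk == 0) {
    if (any(p_mp > 0))
      dmoma_stop("dmoma_validation_error", paste0(
        "nonzero pathway perturbation without a xenobiotic driver ",
        "(P_PBPK = 0) signals an upstream inconsistency"))
    return(stats::setNames(numeric(length(p_mp)), names(p_mp)))
  }
  p_mp / p_pbpk
}

#' Fraction of altered reactions over time
#'
#' @param delta differential flux matrix.
#' @param eps minimal flux threshold; a reaction is altered at a timepoint
#'   when `|delta| > eps`.
#' @return numeric vector, one value in `[0, 1]` per timepoint.
#' @export
altered_fraction <- function(delta, eps) {
  colMeans(abs(delta) > eps)
}

#' Exometabolome pool changes
#'
#' Signed and absolute integrals of the differential exchange fluxes.
#' Internally positive exchange flux secretes the metabolite, so a
#' positive signed integral means the extracellular pool gained the
#' metabolite; `hepatic_utilization` reports the same number in the
#' organ-centric uptake (+) / secretion (-) convention.
#'
#' @param delta differential flux matrix (full; exchange rows are picked
#'   via `roles`).
#' @param dt step width (min).
#' @param roles named role vector of the context network.
#' @return data frame with columns `exchange_id`, `p_ex_abs` (umol),
#'   `pool_change` (signed, umol; + = pool increased),
#'   `hepatic_utilization` (umol, uptake positive), `direction`
#'   (`"increased"`/`"decreased"`/`"unchanged"`).
#' @export
exometabolome_pools <- function(delta, dt, roles) {
  ex <- names(roles)[roles == "exchange"]
  ex <- intersect(rownames(delta), ex)
  if (length(ex) == 0L)
    dmoma_stop("dmoma_validation_error",
               "no exchange reactions in the flux matrix")
  cols <- step_columns(delta)
  sub <- delta[ex, cols, drop = FALSE]
  signed <- rowSums(sub) * dt
  absint <- rowSums(abs(sub)) * dt
  data.frame(
    exchange_id = ex,
    p_ex_abs = absint,
    pool_change = signed,
    hepatic_utilization = -signed,
    direction = ifelse(signed > 0, "increased",
                       ifelse(signed < 0, "decreased", "unchanged")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Full perturbation report for a dMOMA run
#'
#' Computes the whole analytics layer in one pass: differential fluxes,
#' integrated perturbations (per reaction, per exchange, xenobiotic
#' driver), the significance mask, pathway perturbations and scores,
#' per-cluster attenuation curves, the altered-reaction fraction over
#' time, and exometabolome pool changes.
#'
#' Per-step pathway perturbations (the attenuation numerator) use the
#' whole-run significance mask, so the attenuation curve's endpoint
#' equals the pathway total exactly.
#'
#' @param fm a `flux_matrix`.
#' @param clusters named character vector, reaction id -> pathway cluster;
#'   reactions of the context network absent from the table are reported
#'   under cluster `"unclustered"`.
#' @param eps minimal flux threshold (default: the reference state's).
#' @return object of class `perturbation_report`.
#' @export
perturbation_report <- function(fm, clusters = NULL, eps = fm$ref$epsilon) {
  ref <- fm$ref
  roles <- reaction_roles(ref$network)
  delta <- differential_fluxes(fm, ref)
  dt <- fm$dt
  t_total <- fm$times[length(fm$times)] - fm$times[1]

  rids <- rownames(delta)
  if (is.null(clusters)) clusters <- stats::setNames(character(0), character(0))
  bad <- setdiff(names(clusters), rids)
  clusters <- clusters[setdiff(names(clusters), bad)]
  unlab <- setdiff(rids, names(clusters))
  if (length(unlab))
    clusters <- c(clusters,
                  stats::setNames(rep("unclustered", length(unlab)), unlab))

  p_rxn <- integrate_perturbation(delta, dt, "rxn")
  p_ex <- integrate_perturbation(delta, dt, "ex", roles)
  p_pbpk <- integrate_perturbation(delta, dt, "pbpk", roles)
  sig <- significance_mask(p_rxn, eps, t_total)
  p_mp <- pathway_perturbation(p_rxn, sig, clusters)
  scores <- pathway_score(p_mp, p_pbpk)

  # per-step cluster perturbation, global significance mask
  cols <- step_columns(delta)
  at_mp <- list()
  for (cl in names(p_mp)) {
    members <- intersect(names(clusters)[clusters == cl], sig)
    if (length(members) == 0L || p_mp[[cl]] <= 0) next
    per_step <- colSums(abs(delta[members, cols, drop = FALSE])) * dt
    at_mp[[cl]] <- attenuation_curve(per_step, p_mp[[cl]])
  }
  at_mp <- if (length(at_mp)) do.call(rbind, at_mp) else
    matrix(numeric(0), 0, length(cols))

  structure(
    list(p_rxn = p_rxn, p_ex_abs = p_ex, p_pbpk = p_pbpk, p_mp = p_mp,
         pathway_scores = scores, significant = sig,
         at_mp = at_mp, at_times = fm$times[cols + 1L],
         altered_fraction = altered_fraction(delta, eps),
         times = fm$times,
         pools = exometabolome_pools(delta, dt, roles),
         clusters = clusters, eps = eps, t_total = t_total),
    class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat("perturbation_report: ", length(x$p_rxn), " reactions, ",
      length(x$significant), " significant (P_rxn > ",
      format(x$eps * x$t_total), "); P_PBPK = ", format(x$p_pbpk),
      " umol/liver\n", sep = "")
  if (length(x$pathway_scores)) {
    cat("pathway scores:\n")
    print(round(sort(x$pathway_scores, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Compare two dMOMA runs
#'
#' Per-cluster pathway-score differences and per-exchange signed pool
#' differences between two perturbation reports computed on the same
#' network and clustering (e.g. slow minus fast acetylator).
#'
#' @param report_a,report_b `perturbation_report` objects; differences are
#'   `b - a`.
#' @return list with data frames `pathway_scores` (columns `cluster`,
#'   `ps_a`, `ps_b`, `diff`) and `pools` (columns `exchange_id`,
#'   `pool_change_a`, `pool_change_b`, `diff`). Clusters or exchanges
#'   present in only one run are reported with an explicit 0.
#' @export
compare_runs <- function(report_a, report_b) {
  if (!setequal(names(report_a$p_rxn), names(report_b$p_rxn)))
    dmoma_stop("dmoma_validation_error",
               "reports cover different reaction sets")
  cl <- sort(union(names(report_a$pathway_scores),
                   names(report_b$pathway_scores)))
  get0 <- function(v, k) if (k %in% names(v)) v[[k]] else 0
  ps <- data.frame(
    cluster = cl,
    ps_a = vapply(cl, get0, numeric(1), v = report_a$pathway_scores),
    ps_b = vapply(cl, get0, numeric(1), v = report_b$pathway_scores),
    row.names = NULL, stringsAsFactors = FALSE)
  ps$diff <- ps$ps_b - ps$ps_a

  ex <- sort(union(report_a$pools$exchange_id, report_b$pools$exchange_id))
  pa <- stats::setNames(report_a$pools$pool_change, report_a$pools$exchange_id)
  pb <- stats::setNames(report_b$pools$pool_change, report_b$pools$exchange_id)
  pools <- data.frame(
    exchange_id = ex,
    pool_change_a = vapply(ex, get0, numeric(1), v = pa),
    pool_change_b = vapply(ex, get0, numeric(1), v = pb),
    row.names = NULL, stringsAsFactors = FALSE)
  pools$diff <- pools$pool_change_b - pools$pool_change_a
  list(pathway_scores = ps, pools = pools)
}
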