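# Reference-state construction: expression-driven context extraction (iMAT)
# under physiological exchange constraints, followed by intracellular
# flux-sum minimization. The result is the unperturbed reference flux
# distribution v_ref that anchors the dynamic MOMA coupling.

#' Translate gene expression into reaction activity scores
#'
#' Gene intensities are normalized to the maximal expression value and
#' propagated through each reaction's GPR rule (AND -> min, OR -> max).
#' Reactions without a GPR receive no score and are excluded from the
#' active/inactive classification. Genes appearing in GPRs but missing
#' from the profile are treated as unknown (excluded from min/max) with a
#' warning.
#'
#' @param net a `metabolic_network`.
#' @param expr named numeric vector of non-negative gene intensities
#'   (see [read_expression()]).
#' @return an object of class `reaction_score_set`: list with `scores`
#'   (named numeric in `[0, 1]`, scored reactions only) and empty
#'   `active` / `inactive` slots to be filled by [threshold_sets()].
#' @export
reaction_scores <- function(net, expr) {
  if (length(expr) == 0L || all(expr == 0))
    dmoma_stop("dmoma_validation_error", "expression profile has no signal")
  norm <- expr / max(expr)
  asts <- lapply(net$reactions, function(r) gpr_parse(r$gpr))
  used <- unique(unlist(lapply(asts, gpr_genes)))
  unknown <- setdiff(used, names(norm))
  if (length(unknown))
    dmoma_warn(paste0("GPR genes missing from the expression profile: ",
                      paste(unknown, collapse = ", ")))
  scores <- vapply(asts, gpr_eval, numeric(1), scores = norm)
  scores <- scores[!is.na(scores)]
  structure(list(scores = scores, active = character(0),
                 inactive = character(0)),
            class = "reaction_score_set")
}

#' Partition scored reactions into active and inactive sets
#'
#' Thresholds are the 75th and 25th percentiles of the *non-zero* score
#' distribution, computed by linear interpolation on the sorted score
#' vector (R's default quantile type 7). Reactions scoring at or above the
#' 75th percentile form the active set; reactions at or below the 25th
#' percentile, plus all zero-scored reactions, form the inactive set. If
#' the two thresholds coincide (degenerate score distribution), ties are
#' broken toward the active set with a warning.
#'
#' @param scores a `reaction_score_set` from [reaction_scores()].
#' @param active_q,inactive_q percentiles (defaults 0.75 / 0.25).
#' @return the input with `active` and `inactive` filled (disjoint sets).
#' @export
threshold_sets <- function(scores, active_q = 0.75, inactive_q = 0.25) {
  stopifnot(inherits(scores, "reaction_score_set"))
  s <- scores$scores
  nz <- s[s > 0]
  if (length(nz) == 0L)
    dmoma_stop("dmoma_validation_error",
               "all reaction scores are zero: no expression signal")
  hi <- stats::quantile(nz, active_q, names = FALSE, type = 7)
  lo <- stats::quantile(nz, inactive_q, names = FALSE, type = 7)
  active <- names(s)[s >= hi]
  inactive <- names(s)[s <= lo | s == 0]
  overlap <- intersect(active, inactive)
  if (length(overlap)) {
    dmoma_warn(paste0(
      "degenerate score distribution: ", length(overlap),
      " reaction(s) met both thresholds; assigned to the active set"))
    inactive <- setdiff(inactive, active)
  }
  scores$active <- active
  scores$inactive <- inactive
  scores
}

#' Apply fasted-state physiological exchange constraints
#'
#' Closes every exchange reaction, then opens the ones listed in the
#' utilization table with their explicit `(lb, ub)` bounds (internal
#' convention: negative flux = uptake, positive = secretion; a
#' secretion-only exchange therefore has `lb = 0`, an uptake-only exchange
#' `ub = 0`).
#'
#' @param net a `metabolic_network`.
#' @param utilization data frame with columns `exchange_id`, `lb`, `ub`
#'   (see [read_utilization()]).
#' @return the constrained network.
#' @export
apply_fasted_state <- function(net, utilization) {
  cls <- classify_exchanges(net)
  if (nrow(utilization) == 0L)
    dmoma_warn("empty utilization table: all exchanges closed")
  bad <- setdiff(utilization$exchange_id, cls$exchange)
  if (length(bad))
    dmoma_stop("dmoma_validation_error", paste0(
      "utilization table lists non-exchange reaction(s): ",
      paste(bad, collapse = ", ")))
  for (ex in cls$exchange) net <- set_bounds(net, ex, lb = 0, ub = 0)
  for (i in seq_len(nrow(utilization)))
    net <- set_bounds(net, utilization$exchange_id[i],
                      lb = utilization$lb[i], ub = utilization$ub[i])
  net
}

#' Fit a context-specific network with iMAT
#'
#' Solves the iMAT mixed-integer program: maximize the number of active
#' reactions carrying flux of at least `eps` (in either direction) plus the
#' number of inactive reactions with `|v| <= eps`, subject to steady state,
#' the network bounds and a minimal biomass flux. Among the optimal
#' activity patterns, a deterministic secondary LP picks the flux vector of
#' minimal total `|v|` that realizes the pattern, so results are
#' reproducible run-to-run. Reactions that carry `|v| < eps` in the
#' solution *and* cannot reach `|v| >= eps` anywhere in the feasible region
#' (flux variability check) are pruned from the context network; biomass
#' and xenobiotic reactions are never pruned (the latter are opened later
#' by the coupling loop).
#'
#' @param net a `metabolic_network` with physiological bounds applied.
#' @param sets a `reaction_score_set` with `active`/`inactive` filled.
#' @param eps minimal flux threshold (default `1e-5`
#'   \eqn{\mu}mol liver\eqn{^{-1}} min\eqn{^{-1}}); the same threshold
#'   decides "inactive satisfied" (`|v| <= eps`).
#' @param biomass_min minimal biomass flux (default `1e-4`).
#' @param biomass_id biomass reaction id (default: the reaction with role
#'   `"biomass"`).
#' @param prune drop never-active reactions from the context network
#'   (default `TRUE`).
#' @return list with `network` (context network), `flux` (the iMAT flux
#'   vector, named), `objective` (number of satisfied set members),
#'   `active_satisfied`, `inactive_satisfied` (character vectors), and
#'   `pruned` (ids removed from the context network).
#' @export
imat_fit <- function(net, sets, eps = 1e-5, biomass_min = 1e-4,
                     biomass_id = NULL, prune = TRUE) {
  S <- stoichiometric_matrix(net)
  rids <- reaction_ids(net)
  lb <- lower_bounds(net); ub <- upper_bounds(net)
  n <- length(rids)

  if (is.null(biomass_id)) {
    roles <- reaction_roles(net)
    biomass_id <- names(roles)[roles == "biomass"]
    if (length(biomass_id) == 0L) biomass_id <- NULL
    if (length(biomass_id) > 1L) biomass_id <- biomass_id[1]
  }
  if (!is.null(biomass_id)) {
    bi <- match(biomass_id, rids)
    lb[bi] <- max(lb[bi], biomass_min)
    if (lb[bi] > ub[bi])
      dmoma_stop("dmoma_infeasible_error", paste0(
        "biomass minimum ", biomass_min, " exceeds the upper bound of '",
        biomass_id, "'"))
  }

  active <- intersect(sets$active, rids)
  inactive <- intersect(sets$inactive, rids)

  # --- assemble the MILP ------------------------------------------------
  # variables: [v (n)] + binaries; constraint rows collected as <= rows
  bin_meta <- list()   # list of (rid, kind: plus/minus/zero)
  A_le <- NULL; b_le <- NULL
  add_row <- function(row_v, coef_bin, bin_idx, rhs) {
    row <- c(row_v, numeric(length(bin_meta)))
    row[n + bin_idx] <- coef_bin
    list(row = row, rhs = rhs)
  }
  rows <- list()
  for (rid in active) {
    i <- match(rid, rids)
    # forward indicator: y+ = 1  =>  v_i >= eps
    bin_meta[[length(bin_meta) + 1L]] <- list(rid = rid, kind = "plus")
    jp <- length(bin_meta)
    #   -v_i + (eps - lb_i) y+ <= -lb_i
    ev <- numeric(n); ev[i] <- -1
    rows[[length(rows) + 1L]] <- list(v = ev, j = jp,
                                      c = eps - lb[i], rhs = -lb[i])
    if (lb[i] < -eps) {
      # reverse indicator: y- = 1  =>  v_i <= -eps
      bin_meta[[length(bin_meta) + 1L]] <- list(rid = rid, kind = "minus")
      jm <- length(bin_meta)
      ev <- numeric(n); ev[i] <- 1
      rows[[length(rows) + 1L]] <- list(v = ev, j = jm,
                                        c = eps + ub[i], rhs = ub[i])
      # y+ + y- <= 1
      rows[[length(rows) + 1L]] <- list(v = numeric(n), j = c(jp, jm),
                                        c = c(1, 1), rhs = 1)
    }
  }
  for (rid in inactive) {
    i <- match(rid, rids)
    bin_meta[[length(bin_meta) + 1L]] <- list(rid = rid, kind = "zero")
    j0 <- length(bin_meta)
    # y0 = 1  =>  -eps <= v_i <= eps
    ev <- numeric(n); ev[i] <- 1
    rows[[length(rows) + 1L]] <- list(v = ev, j = j0,
                                      c = ub[i] - eps, rhs = ub[i])
    ev <- numeric(n); ev[i] <- -1
    rows[[length(rows) + 1L]] <- list(v = ev, j = j0,
                                      c = -(lb[i] + eps), rhs = -lb[i])
  }
  nb <- length(bin_meta)
  if (nb > 0L) {
    A_le <- matrix(0, length(rows), n + nb)
    b_le <- numeric(length(rows))
    for (k in seq_along(rows)) {
      A_le[k, seq_len(n)] <- rows[[k]]$v
      A_le[k, n + rows[[k]]$j] <- rows[[k]]$c
      b_le[k] <- rows[[k]]$rhs
    }
  }
  A_eq <- cbind(S, matrix(0, nrow(S), nb))
  b_eq <- rep(0, nrow(S))

  # objective: one point per satisfied binary, with a tiny index-decreasing
  # weight so the optimum is unique and the search deterministic
  obj <- c(numeric(n),
           if (nb) 1 - 1e-9 * seq_len(nb) else numeric(0))
  lb_all <- c(lb, rep(0, nb)); ub_all <- c(ub, rep(1, nb))

  if (nb == 0L) {
    base <- solve_lp(numeric(n), lb, ub, A_eq = S, b_eq = b_eq)
    if (base$status != "optimal")
      dmoma_stop("dmoma_infeasible_error", paste0(
        "network infeasible under physiological bounds",
        if (!is.null(biomass_id)) paste0(" and biomass minimum (check '",
                                         biomass_id, "')")))
    v <- stats::setNames(base$x[seq_len(n)], rids)
    return(list(network = net, flux = v, objective = 0,
                active_satisfied = character(0),
                inactive_satisfied = character(0), pruned = character(0)))
  }

  mip <- milp_maximize(obj, lb_all, ub_all, A_eq, b_eq, A_le, b_le,
                       bin_idx = n + seq_len(nb))
  if (is.null(mip$x))
    dmoma_stop("dmoma_infeasible_error", paste0(
      "iMAT problem infeasible under the physiological bounds",
      if (!is.null(biomass_id)) paste0(" and biomass minimum '",
                                       biomass_id, "' >= ", biomass_min)))
  y <- mip$x[n + seq_len(nb)] > 0.5
  v0 <- mip$x[seq_len(n)]
  kinds <- vapply(bin_meta, `[[`, character(1), "kind")
  brids <- vapply(bin_meta, `[[`, character(1), "rid")
  act_sat <- unique(brids[y & kinds %in% c("plus", "minus")])
  inact_sat <- brids[y & kinds == "zero"]
  objective <- length(act_sat) + length(inact_sat)
  if (length(active) && length(act_sat) == 0L)
    dmoma_warn("no active reaction can carry a flux of eps: threshold too large for this network")

  # --- deterministic flux extraction: min total |v| over the pattern ----
  lb2 <- lb; ub2 <- ub
  for (k in which(y)) {
    i <- match(brids[k], rids)
    if (kinds[k] == "plus") lb2[i] <- max(lb2[i], eps)
    else if (kinds[k] == "minus") ub2[i] <- min(ub2[i], -eps)
    else { lb2[i] <- max(lb2[i], -eps); ub2[i] <- min(ub2[i], eps) }
  }
  v <- minimize_total_flux(S, lb2, ub2, which_abs = seq_len(n))
  if (is.null(v)) v <- v0
  v <- stats::setNames(v, rids)

  # --- pruning ----------------------------------------------------------
  pruned <- character(0)
  if (prune) {
    roles <- reaction_roles(net)
    cand <- rids[abs(v) < eps & !roles %in% c("biomass", "xenobiotic")]
    if (length(cand)) {
      # the variability check opens the (currently closed) xenobiotic
      # reactions: machinery that only serves the drug metabolism must
      # survive extraction, or the coupling loop would hit a pruned wall
      ub_f <- ub
      ub_f[roles == "xenobiotic"] <- pmax(ub_f[roles == "xenobiotic"], 1000)
      rng <- flux_variability(S, lb, ub_f, match(cand, rids))
      blocked <- pmax(abs(rng[, "min"]), abs(rng[, "max"])) < eps
      pruned <- cand[blocked]
    }
    if (length(pruned)) {
      net$reactions <- net$reactions[setdiff(rids, pruned)]
      used <- unique(unlist(lapply(net$reactions,
                                   function(r) names(r$stoichiometry))))
      net$metabolites <- net$metabolites[net$metabolites$id %in% used, ]
      v <- v[setdiff(rids, pruned)]
    }
  }
  list(network = net, flux = v, objective = objective,
       active_satisfied = act_sat, inactive_satisfied = inact_sat,
       pruned = pruned)
}

# min sum_{j in which_abs} |v_j|  s.t.  S v = 0, lb <= v <= ub
# via epigraph variables t_j >= |v_j|. Returns the v part or NULL.
minimize_total_flux <- function(S, lb, ub, which_abs) {
  n <- ncol(S); k <- length(which_abs)
  obj <- c(numeric(n), rep(1, k))
  # t_j >= v_j  and t_j >= -v_j  as <= rows
  A1 <- matrix(0, k, n + k); A2 <- matrix(0, k, n + k)
  for (q in seq_len(k)) {
    A1[q, which_abs[q]] <- 1;  A1[q, n + q] <- -1   #  v - t <= 0
    A2[q, which_abs[q]] <- -1; A2[q, n + q] <- -1   # -v - t <= 0
  }
  tmax <- pmax(abs(lb[which_abs]), abs(ub[which_abs]))
  res <- solve_lp(obj, lb = c(lb, rep(0, k)), ub = c(ub, tmax),
                  A_eq = cbind(S, matrix(0, nrow(S), k)),
                  b_eq = rep(0, nrow(S)),
                  A_le = rbind(A1, A2), b_le = rep(0, 2 * k))
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' Minimize intracellular fluxes around an iMAT solution
#'
#' Finds the flux vector of minimal intracellular flux sum
#' \eqn{\sum_j |v_j|} that keeps (i) every exchange flux exactly at its
#' iMAT value and (ii) the direction of every reaction that carries
#' `|v| >= eps` in the iMAT solution. This realizes the assumption that
#' cells reduce pathway usage to an efficient minimum, and in particular
#' drains thermodynamically meaningless loop fluxes to zero.
#'
#' @param net the context network returned by [imat_fit()].
#' @param v_imat the iMAT flux vector (named numeric over `net`'s
#'   reactions).
#' @param eps directionality threshold (default `1e-5`).
#' @return an object of class `reference_state`: list with `network`,
#'   `v_ref` (a [flux_distribution()]), `epsilon`, `fixed_directions`
#'   (named sign vector for the direction-locked reactions) and
#'   `biomass_id`.
#' @export
minimize_intracellular_flux <- function(net, v_imat, eps = 1e-5) {
  S <- stoichiometric_matrix(net)
  rids <- reaction_ids(net)
  if (!all(rids %in% names(v_imat)))
    dmoma_stop("dmoma_validation_error",
               "v_imat does not cover the context network's reactions")
  v_imat <- v_imat[rids]
  lb <- lower_bounds(net); ub <- upper_bounds(net)
  cls <- classify_exchanges(net)
  ex_idx <- match(cls$exchange, rids)
  int_idx <- match(cls$intracellular, rids)

  lb2 <- lb; ub2 <- ub
  lb2[ex_idx] <- ub2[ex_idx] <- v_imat[ex_idx]
  locked <- abs(v_imat) >= eps
  dirs <- sign(v_imat)[locked]
  for (i in which(locked)) {
    if (v_imat[i] > 0) lb2[i] <- max(lb2[i], 0) else ub2[i] <- min(ub2[i], 0)
  }
  v <- minimize_total_flux(S, lb2, ub2, which_abs = int_idx)
  if (is.null(v)) {
    bad <- diagnose_infeasibility(S, lb2, ub2)
    dmoma_stop("dmoma_infeasible_error", paste0(
      "flux minimization infeasible; binding metabolite balance(s): ",
      paste(bad, collapse = ", ")))
  }
  v <- stats::setNames(v, rids)

  roles <- reaction_roles(net)
  biomass_id <- names(roles)[roles == "biomass"]
  structure(
    list(network = net,
         v_ref = flux_distribution(v, net),
         epsilon = eps,
         fixed_directions = dirs,
         biomass_id = if (length(biomass_id)) biomass_id[1] else NULL),
    class = "reference_state")
}

#' Build the unperturbed reference state in one call
#'
#' Convenience wrapper chaining [apply_fasted_state()],
#' [reaction_scores()], [threshold_sets()], [imat_fit()] and
#' [minimize_intracellular_flux()].
#'
#' @param net a (xenobiotic-extended) `metabolic_network`.
#' @param expr named gene-intensity vector.
#' @param utilization exchange-utilization data frame.
#' @param eps minimal flux threshold (default `1e-5`).
#' @param biomass_min minimal biomass flux (default `1e-4`).
#' @param ... passed on to [imat_fit()].
#' @return a `reference_state`.
#' @export
build_reference_state <- function(net, expr, utilization,
                                  eps = 1e-5, biomass_min = 1e-4, ...) {
  net <- apply_fasted_state(net, utilization)
  sets <- threshold_sets(reaction_scores(net, expr))
  fit <- imat_fit(net, sets, eps = eps, biomass_min = biomass_min, ...)
  minimize_intracellular_flux(fit$network, fit$flux, eps = eps)
}

#' @export
print.reference_state <- function(x, ...) {
  cat("reference_state over ", length(x$v_ref), " reactions (epsilon = ",
      format(x$epsilon), ", ", length(x$fixed_directions),
      " locked directions)\n", sep = "")
  invisible(x)
}
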