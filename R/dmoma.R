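# The coupling engine: at every timepoint, pin the pharmacokinetic
# xenobiotic reaction rates into the network and solve the minimization-
# of-metabolic-adjustment quadratic program
#
#     min (v - v_ref)' (v - v_ref)
#     s.t. S v = 0,  lb <= v <= ub,  v_xenobiotic = v_PBPK(t)
#
# against the same unperturbed reference v_ref at each step. The QP is
# strictly convex, so each column of the resulting flux matrix is the
# unique closest feasible flux distribution to the reference.

#' Pin pharmacokinetic rates into xenobiotic reactions
#'
#' Sets `lower_bound = upper_bound = rate` for each named xenobiotic
#' reaction; all other bounds are untouched.
#'
#' @param net a `metabolic_network`.
#' @param rates named numeric vector, xenobiotic reaction id -> flux.
#' @return the pinned network.
#' @export
pin_xenobiotic <- function(net, rates) {
  roles <- reaction_roles(net)
  for (rid in names(rates)) {
    if (!rid %in% names(roles))
      dmoma_stop("dmoma_validation_error",
                 paste0("unknown reaction '", rid, "'"))
    if (roles[[rid]] != "xenobiotic")
      dmoma_stop("dmoma_validation_error", paste0(
        "reaction '", rid, "' has role '", roles[[rid]],
        "': only xenobiotic reactions may be pinned"))
    net <- set_bounds(net, rid, lb = rates[[rid]], ub = rates[[rid]])
  }
  net
}

#' Solve one MOMA step
#'
#' Finds the unique flux distribution closest (Euclidean) to the reference
#' among all steady-state flux vectors respecting the (pinned) bounds.
#' Pinned xenobiotic components equal the driving rates exactly.
#'
#' @param net the pinned `metabolic_network`.
#' @param ref a `reference_state` (its `v_ref` is the anchor).
#' @return a [flux_distribution()]. On infeasibility an error of condition
#'   class `dmoma_infeasible_step` is thrown whose `metabolites` field
#'   names the conflicting metabolite balances.
#' @export
solve_moma_step <- function(net, ref) {
  stopifnot(inherits(ref, "reference_state"))
  rids <- reaction_ids(net)
  if (!setequal(rids, names(ref$v_ref)))
    dmoma_stop("dmoma_validation_error",
               "network and reference state cover different reactions")
  S <- stoichiometric_matrix(net)
  lb <- lower_bounds(net); ub <- upper_bounds(net)
  sol <- solve_qp_projection(S, as.numeric(ref$v_ref[rids]), lb, ub)
  if (sol$status != "optimal") {
    bad <- diagnose_infeasibility(S, lb, ub)
    dmoma_stop("dmoma_infeasible_step", paste0(
      "MOMA step infeasible; conflicting metabolite balance(s): ",
      paste(bad, collapse = ", ")), metabolites = bad)
  }
  flux_distribution(stats::setNames(sol$v, rids), net)
}

#' Run the dynamic MOMA coupling over a rate series
#'
#' Iterates over the time grid of the driving series: pins the xenobiotic
#' rates of timepoint i into the network and solves the MOMA QP against
#' the *original* reference state (each step is independent given
#' `v_ref`). Xenobiotic reactions without a column in the series are held
#' at zero. Consecutive timepoints with identical rate vectors reuse the
#' previous solution (the QP is strictly convex, so this is exact, not an
#' approximation).
#'
#' @param ref a `reference_state`.
#' @param series a `rate_time_series`; its reaction ids must be xenobiotic
#'   reactions of the reference network.
#' @param relax if `TRUE`, an infeasible step is retried with the pinned
#'   rate vector uniformly scaled by the largest feasible factor
#'   `alpha in [0, 1]` (bisection); the applied factors are recorded in
#'   the result. Default `FALSE`: infeasibility is a hard error carrying
#'   the timepoint index and the partial flux matrix.
#' @param progress_every log progress every N steps (0 = silent).
#' @return object of class `flux_matrix`: list with `fluxes` (reactions x
#'   timepoints matrix), `times`, `dt`, `ref`, and `alpha` (per-timepoint
#'   relaxation factors, all 1 unless `relax` triggered).
#' @export
run_dmoma <- function(ref, series, relax = FALSE, progress_every = 0) {
  stopifnot(inherits(ref, "reference_state"),
            inherits(series, "rate_time_series"))
  net <- ref$network
  roles <- reaction_roles(net)
  xeno <- names(roles)[roles == "xenobiotic"]
  driven <- colnames(series$rates)
  bad <- setdiff(driven, xeno)
  if (length(bad))
    dmoma_stop("dmoma_validation_error", paste0(
      "rate series drives non-xenobiotic reaction(s): ",
      paste(bad, collapse = ", ")))
  # undriven xenobiotic reactions are held closed at 0
  pin_ids <- xeno
  rids <- reaction_ids(net)
  S <- stoichiometric_matrix(net)
  lb0 <- lower_bounds(net); ub0 <- upper_bounds(net)
  vref <- as.numeric(ref$v_ref[rids])
  pin_idx <- match(pin_ids, rids)

  nt <- length(series$times)
  fm <- matrix(NA_real_, length(rids), nt,
               dimnames = list(rids, NULL))
  alpha <- rep(1, nt)
  prev_rates <- NULL; prev_v <- NULL

  for (i in seq_len(nt)) {
    rates <- stats::setNames(rep(0, length(pin_ids)), pin_ids)
    rates[driven] <- series$rates[i, driven]
    if (!is.null(prev_rates) && isTRUE(all(rates == prev_rates))) {
      fm[, i] <- prev_v
      next
    }
    if (all(rates == 0) && all(vref[pin_idx] == 0)) {
      # v_ref itself is feasible with objective 0, hence the unique
      # minimizer: no QP needed, the column is exactly the reference
      fm[, i] <- vref
      prev_rates <- rates; prev_v <- vref
      next
    }
    solve_at <- function(a) {
      lb <- lb0; ub <- ub0
      lb[pin_idx] <- ub[pin_idx] <- a * rates
      solve_qp_projection(S, vref, lb, ub)
    }
    sol <- solve_at(1)
    if (sol$status != "optimal" && relax) {
      lo <- 0; hi <- 1
      base <- solve_at(0)
      if (base$status != "optimal")
        dmoma_stop("dmoma_infeasible_step",
                   paste0("network infeasible even with zero rates at ",
                          "timepoint ", i),
                   timepoint = i, partial = fm[, seq_len(i - 1), drop = FALSE])
      best <- base
      for (k in 1:40) {
        mid <- (lo + hi) / 2
        s <- solve_at(mid)
        if (s$status == "optimal") { lo <- mid; best <- s } else hi <- mid
      }
      alpha[i] <- lo
      sol <- best
    }
    if (sol$status != "optimal") {
      lb <- lb0; ub <- ub0
      lb[pin_idx] <- ub[pin_idx] <- rates
      bad_met <- diagnose_infeasibility(S, lb, ub)
      dmoma_stop("dmoma_infeasible_step", paste0(
        "MOMA step infeasible at timepoint ", i, " (t = ",
        series$times[i], " min); conflicting metabolite balance(s): ",
        paste(bad_met, collapse = ", ")),
        timepoint = i, metabolites = bad_met,
        partial = fm[, seq_len(i - 1), drop = FALSE])
    }
    fm[, i] <- sol$v
    prev_rates <- rates; prev_v <- sol$v
    if (progress_every > 0 && i %% progress_every == 0)
      message("dMOMA step ", i, "/", nt)
  }
  structure(list(fluxes = fm, times = series$times, dt = series$dt,
                 ref = ref, alpha = alpha),
            class = "flux_matrix")
}

#' @export
print.flux_matrix <- function(x, ...) {
  cat("flux_matrix: ", nrow(x$fluxes), " reactions x ", ncol(x$fluxes),
      " timepoints (dt = ", x$dt, " min)\n", sep = "")
  invisible(x)
}

#' Serialize a flux matrix to CSV (+ JSON sidecar)
#'
#' @param fm a `flux_matrix`.
#' @param path output CSV path (reactions x timepoints); a `.json` sidecar
#'   with the grid and solver metadata is written next to it.
#' @return `path`, invisibly.
#' @export
write_flux_matrix <- function(fm, path) {
  tab <- data.frame(reaction_id = rownames(fm$fluxes), fm$fluxes,
                    check.names = FALSE)
  colnames(tab)[-1] <- as.character(fm$times)
  utils::write.csv(tab, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(times = fm$times, dt = fm$dt,
         n_reactions = nrow(fm$fluxes),
         epsilon = fm$ref$epsilon,
         alpha = fm$alpha,
         solver = "quadprog (Goldfarb-Idnani dual active set)"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
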