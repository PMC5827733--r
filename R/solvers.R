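# Linear and quadratic programming kernels.
#
# LP: own dense bounded-variable revised simplex (lp_simplex.R).
# Inequality rows get slack variables; linearly dependent equality rows
# (stoichiometric matrices routinely carry conservation dependencies) are
# dropped by QR after a consistency check.
#
# QP: quadprog::solve.QP (Goldfarb-Idnani dual active set), with the same
# equality rank-reduction, which solve.QP does not tolerate either.

solve_lp <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  if (!is.null(A_eq)) {
    qa <- qr(t(A_eq))
    if (qa$rank < nrow(A_eq)) {
      if (qr(t(cbind(A_eq, b_eq)))$rank > qa$rank)
        return(list(status = "infeasible", x = NULL, value = NA_real_))
      keep <- qa$pivot[seq_len(qa$rank)]
      A_eq <- A_eq[keep, , drop = FALSE]; b_eq <- b_eq[keep]
    }
  }
  n_sl <- if (is.null(A_le)) 0L else nrow(A_le)
  A <- rbind(
    if (!is.null(A_eq)) cbind(A_eq, matrix(0, nrow(A_eq), n_sl)),
    if (n_sl) cbind(A_le, diag(1, n_sl)))
  b <- c(b_eq, b_le)
  if (is.null(A)) {  # pure box problem
    x <- ifelse((if (maximize) obj else -obj) > 0, ub, lb)
    return(list(status = "optimal", x = stats::setNames(x, names(obj)),
                value = sum(obj * x)))
  }
  cc <- c(if (maximize) -obj else obj, rep(0, n_sl))
  res <- simplex_bounded(cc, A, b,
                         lo = c(lb, rep(0, n_sl)),
                         hi = c(ub, rep(Inf, n_sl)))
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_))
  x <- res$x[seq_len(n)]
  list(status = "optimal", x = stats::setNames(x, names(obj)),
       value = sum(obj * x))
}

# Euclidean-closest feasible flux vector:
#   min ||v - vref||^2  s.t.  S v = 0,  lb <= v <= ub
# Reactions with lb == ub (pinned) are folded into the equality system.
solve_qp_projection <- function(S, vref, lb, ub, tol = 1e-8) {
  n <- length(vref)
  pinned <- which(abs(ub - lb) < .Machine$double.eps * 16)
  E <- S; e <- rep(0, nrow(S))
  if (length(pinned)) {
    P <- matrix(0, length(pinned), n)
    P[cbind(seq_along(pinned), pinned)] <- 1
    E <- rbind(E, P); e <- c(e, (lb[pinned] + ub[pinned]) / 2)
  }
  qE <- qr(t(E))
  keep <- qE$pivot[seq_len(qE$rank)]
  E2 <- E[keep, , drop = FALSE]; e2 <- e[keep]

  free <- setdiff(seq_len(n), pinned)
  Amat <- cbind(t(E2),
                diag(1, n)[, free, drop = FALSE],
                -diag(1, n)[, free, drop = FALSE])
  bvec <- c(e2, lb[free], -ub[free])
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(2, n), dvec = 2 * vref,
                       Amat = Amat, bvec = bvec, meq = nrow(E2)),
    error = function(err) {
      if (grepl("inconsistent", conditionMessage(err)))
        return(NULL)
      dmoma_stop("dmoma_solver_error", paste0(
        "QP solver failed: ", conditionMessage(err)))
    })
  if (is.null(sol))
    return(list(status = "infeasible", v = NULL))
  v <- sol$solution
  # residual over the *full* (pre-rank-reduction) equality system: a
  # dropped dependent row with inconsistent rhs means true infeasibility
  if (max(abs(E %*% v - e)) > max(tol, 1e-7))
    return(list(status = "infeasible", v = NULL))
  v <- pmin(pmax(v, lb), ub)   # clip 1e-12-scale bound round-off
  list(status = "optimal", v = v)
}

# Flux variability: min and max of each requested reaction's flux under
# S v = 0 and the bounds.
flux_variability <- function(S, lb, ub, idx = seq_len(ncol(S))) {
  n <- ncol(S)
  out <- matrix(NA_real_, length(idx), 2,
                dimnames = list(colnames(S)[idx], c("min", "max")))
  for (k in seq_along(idx)) {
    obj <- rep(0, n); obj[idx[k]] <- 1
    lo <- solve_lp(obj, lb, ub, A_eq = S, b_eq = rep(0, nrow(S)))
    hi <- solve_lp(obj, lb, ub, A_eq = S, b_eq = rep(0, nrow(S)),
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      dmoma_stop("dmoma_solver_error", paste0(
        "flux variability LP failed for reaction index ", idx[k]))
    out[k, ] <- c(lo$x[idx[k]], hi$x[idx[k]])
  }
  out
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum achievable flux under steady state
#' (`S v = 0`) and the network's bounds.
#'
#' @param net a `metabolic_network`.
#' @param reactions reaction ids to analyze (default: all).
#' @return matrix with rows = reactions, columns `min`, `max`.
#' @export
fva <- function(net, reactions = NULL) {
  S <- stoichiometric_matrix(net)
  rids <- reaction_ids(net)
  reactions <- reactions %||% rids
  idx <- match(reactions, rids)
  if (anyNA(idx))
    dmoma_stop("dmoma_validation_error", paste0(
      "unknown reactions: ", paste(reactions[is.na(idx)], collapse = ", ")))
  flux_variability(S, lower_bounds(net), upper_bounds(net), idx)
}

# Phase-1 style diagnosis: which metabolite balances need slack for the
# constraint system to become feasible? Returns a character vector of
# metabolite ids (empty if the system is feasible as stated).
diagnose_infeasibility <- function(S, lb, ub) {
  m <- nrow(S); n <- ncol(S)
  if (any(lb > ub))
    return(structure(character(0),
                     bad_bounds = colnames(S)[which(lb > ub)]))
  obj <- c(rep(0, n), rep(1, 2 * m))
  A_eq <- cbind(S, diag(1, m), diag(-1, m))
  res <- solve_lp(obj, lb = c(lb, rep(0, 2 * m)),
                  ub = c(ub, rep(1e6, 2 * m)),
                  A_eq = A_eq, b_eq = rep(0, m))
  if (res$status != "optimal")
    return(rownames(S))  # cannot localize; implicate all balances
  slack <- abs(res$x[(n + 1):(n + m)]) + abs(res$x[(n + m + 1):(n + 2 * m)])
  rownames(S)[slack > 1e-7]
}
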