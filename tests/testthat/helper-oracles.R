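# Independent oracles, kept deliberately separate from the package's
# solver path.

# Analytic solution of  min ||v - vref||^2  s.t.  S v = 0, v[pin] = r,
# assuming no inequality bound is active: the equality-constrained
# least-squares projection via the Moore-Penrose pseudoinverse.
kkt_project <- function(S, vref, pin_idx = integer(0), rates = numeric(0)) {
  n <- length(vref)
  E <- S
  e <- rep(0, nrow(S))
  if (length(pin_idx)) {
    P <- matrix(0, length(pin_idx), n)
    P[cbind(seq_along(pin_idx), pin_idx)] <- 1
    E <- rbind(E, P)
    e <- c(e, rates)
  }
  as.numeric(vref - t(E) %*% MASS::ginv(E %*% t(E)) %*% (E %*% vref - e))
}

# Brute-force iMAT: enumerate every subset of the active and inactive
# sets and test feasibility of the implied flux constraints with the
# Goldfarb-Idnani QP (a feasible point exists iff the projection of 0
# onto the constraint set succeeds) -- a code path independent of the
# package's simplex/branch-and-bound. Active reactions must be
# irreversible (forward), which all test networks honor.
imat_brute_force <- function(net, sets, eps = 1e-5, biomass_min = 1e-4) {
  S <- stoichiometric_matrix(net)
  rids <- reaction_ids(net)
  lb <- lower_bounds(net); ub <- upper_bounds(net)
  roles <- reaction_roles(net)
  bi <- match(names(roles)[roles == "biomass"][1], rids)
  if (!is.na(bi)) lb[bi] <- max(lb[bi], biomass_min)
  active <- intersect(sets$active, rids)
  inactive <- intersect(sets$inactive, rids)
  stopifnot(all(lb[match(active, rids)] >= 0))  # irreversible actives only

  feasible <- function(lb2, ub2) {
    sol <- dmoma:::solve_qp_projection(S, numeric(ncol(S)), lb2, ub2)
    identical(sol$status, "optimal")
  }
  best <- -1L
  n_a <- length(active); n_i <- length(inactive)
  for (mask in 0:(2^(n_a + n_i) - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n_a + n_i)]
    sat_a <- active[bits[seq_len(n_a)] == 1L]
    sat_i <- if (n_i) inactive[bits[n_a + seq_len(n_i)] == 1L] else character(0)
    score <- length(sat_a) + length(sat_i)
    if (score <= best) next
    lb2 <- lb; ub2 <- ub
    for (r in sat_a) lb2[match(r, rids)] <- max(lb2[match(r, rids)], eps)
    for (r in sat_i) {
      i <- match(r, rids)
      lb2[i] <- max(lb2[i], -eps); ub2[i] <- min(ub2[i], eps)
    }
    if (all(lb2 <= ub2) && feasible(lb2, ub2)) best <- score
  }
  best
}

# Left-rectangle integral of a trajectory row (the final grid point
# closes the last interval).
lr_integral <- function(values, dt) sum(values[-length(values)]) * dt
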