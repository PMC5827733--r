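# Dense bounded-variable revised simplex.
#
# Solves   min c'x   s.t.  A x = b,  l <= x <= u   (phase 1 + phase 2).
# Written for the moderate problem sizes of this package (<= a few
# hundred variables): the basis inverse is kept explicitly and updated by
# rank-1 elimination, with periodic refactorization against drift.
# Entering variables are chosen by the Dantzig rule with a Bland fallback
# once the objective stalls, which guarantees termination on degenerate
# problems. Tolerances are absolute; constraint matrices here have O(1)
# coefficients.

simplex_bounded <- function(cc, A, b, lo, hi,
                            tol = 1e-9, piv_tol = 1e-10,
                            max_iter = 20000L, refactor_every = 50L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m,
            length(lo) == n, length(hi) == n)
  if (any(lo > hi + tol)) return(list(status = "infeasible"))

  # --- phase 1: artificial basis --------------------------------------
  x <- ifelse(is.finite(lo), lo, ifelse(is.finite(hi), hi, 0))
  resid <- b - as.vector(A %*% x)
  sgn <- ifelse(resid >= 0, 1, -1)
  Aext <- cbind(A, diag(sgn, m))
  lo1 <- c(lo, rep(0, m)); hi1 <- c(hi, rep(Inf, m))
  x1 <- c(x, abs(resid))
  basis <- n + seq_len(m)
  at_upper <- c(!is.finite(lo) & is.finite(hi), rep(FALSE, m))

  run <- function(cost, x, basis, at_upper, lo, hi) {
    nn <- length(cost)
    refactor <- function(basis) {
      B <- Aext[, basis, drop = FALSE]
      qb <- qr(B)
      if (qb$rank < m) return(NULL)
      solve(qb)
    }
    Binv <- refactor(basis)
    if (is.null(Binv)) return(list(status = "singular"))
    since_factor <- 0L
    stalled <- 0L
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      if (since_factor >= refactor_every) {
        Bi <- refactor(basis)
        if (!is.null(Bi)) Binv <- Bi
        since_factor <- 0L
      }
      y <- as.vector(crossprod(Binv, cost[basis]))
      nonbasic <- setdiff(seq_len(nn), basis)
      d <- cost[nonbasic] - as.vector(y %*% Aext[, nonbasic, drop = FALSE])
      up <- at_upper[nonbasic]
      viol <- ifelse(up, d, -d)          # positive = eligible
      eligible <- which(viol > tol)
      if (length(eligible) == 0L)
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper, Binv = Binv))
      obj <- sum(cost * x)
      if (obj < obj_prev - tol) { stalled <- 0L; obj_prev <- obj }
      else stalled <- stalled + 1L
      pick <- if (stalled > 2L * m + 20L)
        eligible[which.min(nonbasic[eligible])]   # Bland
      else eligible[which.max(viol[eligible])]    # Dantzig
      j <- nonbasic[pick]
      sigma <- if (at_upper[j]) -1 else 1         # direction of x_j
      w <- as.vector(Binv %*% Aext[, j])
      # ratio test: basic variables move by -sigma * t * w
      t_max <- hi[j] - lo[j]                      # bound flip distance
      leave <- 0L; leave_to_upper <- FALSE
      for (k in seq_len(m)) {
        wk <- sigma * w[k]
        xi <- x[basis[k]]
        if (wk > piv_tol) {
          lim <- (xi - lo[basis[k]]) / wk
          if (lim < t_max - 1e-12) { t_max <- max(lim, 0); leave <- k
            leave_to_upper <- FALSE }
        } else if (wk < -piv_tol) {
          lim <- (hi[basis[k]] - xi) / (-wk)
          if (lim < t_max - 1e-12) { t_max <- max(lim, 0); leave <- k
            leave_to_upper <- TRUE }
        }
      }
      if (!is.finite(t_max))
        return(list(status = "unbounded"))
      # apply the step
      x[basis] <- x[basis] - sigma * t_max * w
      x[j] <- x[j] + sigma * t_max
      if (leave == 0L) {                          # bound flip, basis keeps
        at_upper[j] <- !at_upper[j]
        next
      }
      out <- basis[leave]
      at_upper[out] <- leave_to_upper
      x[out] <- if (leave_to_upper) hi[out] else lo[out]
      basis[leave] <- j
      at_upper[j] <- FALSE
      # rank-1 update of Binv: eliminate column w in position `leave`
      pv <- w[leave]
      if (abs(pv) < piv_tol) {
        Bi <- refactor(basis)
        if (is.null(Bi)) return(list(status = "singular"))
        Binv <- Bi; since_factor <- 0L
      } else {
        Brow <- Binv[leave, ] / pv
        Binv <- Binv - outer(w, Brow)
        Binv[leave, ] <- Brow
        since_factor <- since_factor + 1L
      }
    }
    list(status = "iteration_limit")
  }

  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run(cost1, x1, basis, at_upper, lo1, hi1)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  if (sum(cost1 * ph1$x) > 1e-7) return(list(status = "infeasible"))

  # phase 2: artificials pinned to zero, original costs
  hi1[n + seq_len(m)] <- 0
  ph2 <- run(c(cc, rep(0, m)), ph1$x, ph1$basis, ph1$at_upper, lo1, hi1)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  xx <- ph2$x[seq_len(n)]
  xx <- pmin(pmax(xx, lo), hi)
  list(status = "optimal", x = xx, value = sum(cc * xx))
}
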