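# Mixed-integer LP by depth-first branch and bound over the simplex LP
# relaxation. Written for the iMAT problem sizes this package works at
# (tens of binaries); branching is deterministic (most fractional binary,
# 1-branch first since the objective rewards satisfied set members), and a
# node is pruned when its relaxation cannot beat the incumbent by more
# than an integrality tolerance.

milp_maximize <- function(obj, lb, ub, A_eq, b_eq, A_le, b_le, bin_idx,
                          int_tol = 1e-6, gap_tol = 1e-9,
                          max_nodes = 100000L) {
  best <- list(x = NULL, value = -Inf)
  nodes <- 0L

  recurse <- function(lb, ub) {
    if (nodes >= max_nodes)
      dmoma_stop("dmoma_solver_error",
                 "branch-and-bound node limit exceeded")
    nodes <<- nodes + 1L
    rel <- solve_lp(obj, lb, ub, A_eq = A_eq, b_eq = b_eq,
                    A_le = A_le, b_le = b_le, maximize = TRUE)
    if (rel$status != "optimal") return(invisible(NULL))
    if (rel$value <= best$value + gap_tol) return(invisible(NULL))
    frac <- abs(rel$x[bin_idx] - round(rel$x[bin_idx]))
    if (all(frac <= int_tol)) {
      x <- rel$x
      x[bin_idx] <- round(x[bin_idx])
      best <<- list(x = x, value = rel$value)
      return(invisible(NULL))
    }
    j <- bin_idx[which.max(frac)]
    lb1 <- lb; lb1[j] <- 1
    recurse(lb1, ub)
    ub0 <- ub; ub0[j] <- 0
    recurse(lb, ub0)
    invisible(NULL)
  }
  recurse(lb, ub)
  best
}
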