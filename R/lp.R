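# Dense two-phase simplex and branch-and-bound for the small LPs/MILPs that
# constraint-based analysis of desk-scale networks produces. Deterministic by
# construction (Bland's anti-cycling rule, fixed branching order); no RNG.

#' Solve a linear program
#'
#' Solves `min/max obj'x` subject to `A x (dir) rhs` and `lb <= x <= ub`
#' with a dense two-phase simplex using Bland's rule, which guarantees
#' termination and bit-reproducible results on degenerate problems such as
#' steady-state flux cones.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (k x n); may have zero rows.
#' @param dir character vector of constraint directions, each one of
#'   `"="`, `"<="`, `">="`.
#' @param rhs right-hand side (length k).
#' @param lb,ub variable bounds; non-finite values are clamped to
#'   `+/- 1e7`, comfortably beyond any flux bound used here.
#' @param maximize logical; maximize instead of minimize.
#' @param tol pivot tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution in the original variable space) and `obj`.
#' @export
solve_lp <- function(obj, A, dir, rhs, lb, ub, maximize = FALSE,
                     tol = 1e-9) {
  n <- length(obj)
  A <- matrix(as.numeric(A), nrow = length(rhs), ncol = n)
  stopifnot(length(dir) == length(rhs), length(lb) == n, length(ub) == n)
  big <- 1e7
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }

  # shift to y = x - lb >= 0; append upper-bound rows y_i <= ub_i - lb_i
  rhs2 <- rhs - as.numeric(A %*% lb)
  ubr <- ub - lb
  Aall <- rbind(A, diag(n))
  dirall <- c(dir, rep("<=", n))
  rhsall <- c(rhs2, ubr)

  # slack columns for inequalities
  ineq <- which(dirall != "=")
  nslack <- length(ineq)
  k <- nrow(Aall)
  Slk <- matrix(0, k, nslack)
  if (nslack) {
    sgn <- ifelse(dirall[ineq] == "<=", 1, -1)
    Slk[cbind(ineq, seq_len(nslack))] <- sgn
  }
  M0 <- cbind(Aall, Slk)
  b0 <- rhsall
  neg <- b0 < 0
  if (any(neg)) {
    M0[neg, ] <- -M0[neg, , drop = FALSE]
    b0[neg] <- -b0[neg]
  }
  cvec <- c(if (maximize) -obj else obj, rep(0, nslack))

  res <- simplex_two_phase(M0, b0, cvec, tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n), obj = NA_real_))
  }
  x <- res$x[seq_len(n)] + lb
  objval <- sum(obj * x)
  list(status = "optimal", x = x, obj = objval)
}

# Two-phase revised simplex for min c'z, M z = b (b >= 0), z >= 0.
# The basis is refactorized with a fresh solve() at every iteration, so
# roundoff does not accumulate across pivots — essential when eps-scale
# activation rows and big-M indicator rows share one constraint matrix.
simplex_two_phase <- function(M, b, cvec, tol = 1e-9) {
  m <- nrow(M)
  n <- ncol(M)
  if (m == 0L) {
    if (any(cvec < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = rep(0, n), obj = 0))
  }

  run_phase <- function(M, b, cost, basis, barred, max_iter = 20000L,
                        bland_only = FALSE) {
    m <- nrow(M)
    ncols <- ncol(M)
    for (it in seq_len(max_iter)) {
      B <- M[, basis, drop = FALSE]
      Binv_b <- tryCatch(solve(B, b), error = function(e) NULL)
      if (is.null(Binv_b)) return(list(status = "singular"))
      yy <- solve(t(B), cost[basis])
      r <- cost - as.numeric(crossprod(M, yy))
      r[basis] <- 0
      cand <- which(!barred & r < -tol)
      if (!length(cand)) {
        if (min(Binv_b) < -1e-7) {
          return(list(status = "numerical"))  # feasibility drifted
        }
        return(list(status = "optimal", basis = basis, xB = Binv_b,
                    obj = sum(cost[basis] * Binv_b)))
      }
      j <- if (bland_only) cand[1L] else cand[which.min(r[cand])]
      d <- solve(B, M[, j])
      pos <- which(d > 1e-11)  # include small components: skipping them
                               # lets basics drift negative on big-M rows
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- pmax(Binv_b[pos], 0) / d[pos]
      rmin <- min(ratio)
      tiers <- pos[ratio <= rmin + tol]
      i <- if (bland_only) tiers[which.min(basis[tiers])]
           else tiers[which.max(d[tiers])]   # largest pivot for stability
      basis[i] <- j
      if (it > 5000L) bland_only <- TRUE     # anti-cycling fallback
    }
    list(status = "iteration_limit")
  }

  # phase 1: artificial basis; retry with strict Bland pivoting if the
  # fast rule loses feasibility numerically
  M1 <- cbind(M, diag(m))
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(M1, b, cost1, basis = n + seq_len(m),
                   barred = rep(FALSE, n + m))
  if (ph1$status %in% c("numerical", "singular")) {
    ph1 <- run_phase(M1, b, cost1, basis = n + seq_len(m),
                     barred = rep(FALSE, n + m), bland_only = TRUE)
  }
  if (ph1$status != "optimal" || ph1$obj > 1e-7) {
    return(list(status = "infeasible"))
  }
  basis <- ph1$basis

  # eliminate artificials: pivot out where possible, drop redundant rows
  arts_in <- which(basis > n)
  if (length(arts_in)) {
    drop_rows <- integer()
    B <- M1[, basis, drop = FALSE]
    for (i in arts_in) {
      ei <- numeric(m); ei[i] <- 1
      brow <- as.numeric(crossprod(M, solve(t(B), ei)))  # row i of B^-1 M
      j <- which(abs(brow) > 1e-7 & !(seq_len(n) %in% basis))
      if (length(j)) {
        basis[i] <- j[1L]
        B <- M1[, basis, drop = FALSE]
      } else {
        drop_rows <- c(drop_rows, basis[i] - n)  # original row index
      }
    }
    if (length(drop_rows)) {
      basis <- basis[!(basis > n & (basis - n) %in% drop_rows)]
      keep <- setdiff(seq_len(m), drop_rows)
      M <- M[keep, , drop = FALSE]
      b <- b[keep]
      m <- length(keep)
    }
    if (any(basis > n) || length(basis) != m) return(list(status = "singular"))
  }

  ph2 <- run_phase(M, b, cvec, basis, barred = rep(FALSE, n))
  if (ph2$status %in% c("numerical", "singular")) {
    ph2 <- run_phase(M, b, cvec, basis, barred = rep(FALSE, n),
                     bland_only = TRUE)
  }
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "infeasible"))
  x <- rep(0, n)
  x[ph2$basis] <- ph2$xB
  x[x < 0 & x > -1e-7] <- 0
  list(status = "optimal", x = x, obj = sum(cvec * x))
}

#' Solve a mixed-integer linear program with binary variables
#'
#' Depth-first branch-and-bound over [solve_lp()] relaxations. Only binary
#' integer variables are supported, which covers the reaction-inclusion
#' indicators used by the tINIT formulation and the gap-filling MILP.
#' Branching is deterministic (most fractional variable, lowest index on
#' ties, nearest-integer child explored first), so identical inputs always
#' return identical solutions.
#'
#' @inheritParams solve_lp
#' @param binary integer indices of variables restricted to \{0, 1\}.
#' @param gap_tol absolute optimality gap used for pruning.
#' @param max_nodes safety cap on explored nodes.
#' @return list with `status` (`"optimal"`, `"infeasible"`), `x`, `obj`.
#' @export
solve_milp <- function(obj, A, dir, rhs, lb, ub, binary,
                       maximize = FALSE, gap_tol = 1e-6,
                       max_nodes = 200000L) {
  n <- length(obj)
  sgn <- if (maximize) -1 else 1
  lb[binary] <- pmax(lb[binary], 0)
  ub[binary] <- pmin(ub[binary], 1)

  best <- list(obj = Inf, x = NULL)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  int_tol <- 1e-6

  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > max_nodes) break
    rel <- solve_lp(sgn * obj, A, dir, rhs, node$lb, node$ub)
    if (rel$status != "optimal") next
    if (rel$obj >= best$obj - gap_tol) next  # bound
    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (all(frac <= int_tol)) {
      # near-integral relaxations can hide big-M coupling violations
      # (y = v/M can be tiny yet meaningful); certify the incumbent by
      # re-solving with the binaries fixed at their rounded values
      yfix <- round(rel$x[binary])
      flb <- node$lb; fub <- node$ub
      flb[binary] <- yfix; fub[binary] <- yfix
      cert <- solve_lp(sgn * obj, A, dir, rhs, flb, fub)
      if (cert$status == "optimal") {
        if (cert$obj < best$obj - gap_tol) {
          x <- cert$x
          x[binary] <- yfix
          best <- list(obj = cert$obj, x = x)
        }
        next
      }
      # rounding infeasible: branch on the least integral binary
      if (max(frac) <= 0) next  # exactly integral yet infeasible: dead node
    }
    j <- binary[which.max(frac)]
    up_first <- rel$x[j] >= 0.5
    lo <- node; lo$ub[j] <- 0
    hi <- node; hi$lb[j] <- 1
    # push the far child first so the nearest-integer child is explored next
    if (up_first) {
      stack[[length(stack) + 1L]] <- lo
      stack[[length(stack) + 1L]] <- hi
    } else {
      stack[[length(stack) + 1L]] <- hi
      stack[[length(stack) + 1L]] <- lo
    }
  }

  if (is.null(best$x)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), obj = NA_real_))
  }
  list(status = "optimal", x = best$x, obj = sgn * best$obj)
}
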