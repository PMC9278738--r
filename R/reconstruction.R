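# Context-specific subnetwork extraction: flux-consistency checking and
# FASTCORE after Vlassis et al.'s LP7/LP10 scheme, plus a reaction-level
# tINIT MILP. Output is always a binary presence vector over the template
# model's reactions.

# LP7: maximize the number of reactions in J that carry >= eps forward flux.
# Variables [v, z_J]; max sum z, s.t. S v = 0, z_j <= v_j, 0 <= z_j <= eps.
lp7 <- function(S, lb, ub, J, eps) {
  n <- ncol(S)
  nj <- length(J)
  m <- nrow(S)
  A <- cbind(S, matrix(0, m, nj))
  if (nj) {
    cpl <- matrix(0, nj, n + nj)
    cpl[cbind(seq_len(nj), J)] <- 1
    cpl[cbind(seq_len(nj), n + seq_len(nj))] <- -1
    A <- rbind(A, cpl)                     # v_j - z_j >= 0
  }
  dir <- c(rep("=", m), rep(">=", nj))
  rhs <- rep(0, m + nj)
  obj <- c(rep(0, n), rep(1, nj))
  res <- solve_lp(obj, A, dir, rhs, c(lb, rep(0, nj)), c(ub, rep(eps, nj)),
                  maximize = TRUE)
  if (res$status != "optimal") stop("LP7 infeasible: model has no steady state")
  res$x[seq_len(n)]
}

# LP10: minimize total absolute flux over P subject to every reaction in K
# carrying >= 0.99*eps forward flux. Variables [v, t_P]; t_p >= |v_p|.
lp10 <- function(S, lb, ub, K, P, eps) {
  n <- ncol(S)
  np <- length(P)
  m <- nrow(S)
  A <- cbind(S, matrix(0, m, np))
  dir <- rep("=", m); rhs <- rep(0, m)
  if (np) {
    up <- matrix(0, np, n + np)
    up[cbind(seq_len(np), P)] <- 1
    up[cbind(seq_len(np), n + seq_len(np))] <- -1   # v_p - t_p <= 0
    lo <- matrix(0, np, n + np)
    lo[cbind(seq_len(np), P)] <- -1
    lo[cbind(seq_len(np), n + seq_len(np))] <- -1   # -v_p - t_p <= 0
    A <- rbind(A, up, lo)
    dir <- c(dir, rep("<=", 2 * np))
    rhs <- c(rhs, rep(0, 2 * np))
  }
  if (length(K)) {
    kk <- matrix(0, length(K), n + np)
    kk[cbind(seq_along(K), K)] <- 1
    A <- rbind(A, kk)
    dir <- c(dir, rep(">=", length(K)))
    rhs <- c(rhs, rep(0.99 * eps, length(K)))
  }
  obj <- c(rep(0, n), rep(1, np))
  res <- solve_lp(obj, A, dir, rhs, c(lb, rep(0, np)),
                  c(ub, rep(max(abs(c(lb, ub))) + 1, np)))
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' Maximal flux-consistent subnetwork (FASTCC)
#'
#' Iterated LP7 blocks with direction flipping for reversible reactions,
#' after the consistency-checking companion of FASTCORE. A reaction is
#' consistent if it can carry at least `eps` flux (in either direction)
#' in some steady-state distribution of the network.
#'
#' @param model a [metabolic_model()].
#' @param eps flux activation threshold.
#' @return character vector of consistent reaction identifiers.
#' @export
fastcc <- function(model, eps = 1e-4) {
  S <- steady_state_rows(model)
  lb <- model$lb; ub <- model$ub
  n <- ncol(S)
  supp_tol <- 0.99 * eps
  irrev <- lb >= 0
  N <- seq_len(n)
  J <- N[irrev]
  v <- lp7(S, lb, ub, J, eps)
  A <- N[abs(v) >= supp_tol]
  J <- setdiff(setdiff(N, A), J)   # reversibles not yet confirmed
  flipped <- FALSE
  singleton <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1L] else J
    v <- lp7(S, lb, ub, Ji, eps)
    A <- union(A, N[abs(v) >= supp_tol])
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      JiRev <- Ji[!irrev[Ji]]
      if (flipped || !length(JiRev)) {
        flipped <- FALSE
        if (singleton) {
          J <- setdiff(J, Ji)       # blocked
        } else {
          singleton <- TRUE
        }
      } else {
        S[, JiRev] <- -S[, JiRev, drop = FALSE]
        tmp <- lb[JiRev]
        lb[JiRev] <- -ub[JiRev]
        ub[JiRev] <- -tmp
        flipped <- TRUE
      }
    }
  }
  sort(model$reaction_ids[sort(A)])
}

#' FASTCORE context-specific extraction
#'
#' Computes an approximately minimal flux-consistent subnetwork
#' containing a set of core reactions, by alternating LP7 (activate as
#' many pending core reactions as possible) with LP10 (an L1-minimal
#' flux mode through them that recruits as few non-core reactions as
#' possible). Core reactions that are not flux-consistent in the
#' template are dropped with a warning before extraction.
#'
#' @param model a [metabolic_model()] (will be reduced to its consistent
#'   part internally).
#' @param core character vector of core reaction identifiers.
#' @param eps flux activation threshold.
#' @return a `reaction_presence` object: named 0/1 integer vector over
#'   all template reactions with a `provenance` attribute.
#' @export
fastcore <- function(model, core, eps = 1e-4) {
  consistent <- fastcc(model, eps)
  bad <- setdiff(core, consistent)
  if (length(bad)) {
    warning("dropping flux-inconsistent core reaction(s): ",
            paste(bad, collapse = ", "))
    core <- intersect(core, consistent)
  }
  if (!length(core)) stop("effective core is empty after consistency filtering")

  keep <- model$reaction_ids %in% consistent
  S <- steady_state_rows(model)[, keep, drop = FALSE]
  ids <- model$reaction_ids[keep]
  lb <- model$lb[keep]; ub <- model$ub[keep]
  n <- ncol(S)
  N <- seq_len(n)
  irrev <- lb >= 0
  C <- match(core, ids)
  supp_tol <- 0.99 * eps

  find_sparse_mode <- function(J, P, singleton) {
    if (!length(J)) return(integer())
    Jq <- if (singleton) J[1L] else J
    v <- lp7(S, lb, ub, Jq, eps)
    K <- intersect(Jq, N[v >= supp_tol])
    if (!length(K)) return(integer())
    v <- lp10(S, lb, ub, K, P, eps)
    if (is.null(v)) return(integer())
    N[abs(v) >= eps * 1e-6]
  }

  flipped <- FALSE; singleton <- FALSE
  J <- intersect(C, N[irrev])
  P <- setdiff(N, C)
  A <- find_sparse_mode(J, P, FALSE)
  if (length(setdiff(J, A))) {
    stop("inconsistent irreversible core reactions: ",
         paste(ids[setdiff(J, A)], collapse = ", "))
  }
  J <- setdiff(C, A)
  while (length(J)) {
    P <- setdiff(P, A)
    A <- union(A, find_sparse_mode(J, P, singleton))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
      singleton <- FALSE
    } else {
      JiRev <- if (singleton) setdiff(J[1L], N[irrev]) else setdiff(J, N[irrev])
      if (flipped || !length(JiRev)) {
        if (singleton) {
          stop("global network inconsistent: cannot activate core reaction ",
               ids[J[1L]])
        }
        flipped <- FALSE
        singleton <- TRUE
      } else {
        S[, JiRev] <- -S[, JiRev, drop = FALSE]
        tmp <- lb[JiRev]
        lb[JiRev] <- -ub[JiRev]
        ub[JiRev] <- -tmp
        flipped <- TRUE
      }
    }
  }
  present <- ids[sort(A)]
  reaction_presence(model, present,
                    provenance = list(algorithm = "FASTCORE", eps = eps))
}

#' Construct a reaction presence vector
#'
#' @param model template [metabolic_model()].
#' @param present character vector of reaction identifiers kept in the
#'   context-specific model.
#' @param provenance list describing how the vector was produced.
#' @return named integer 0/1 vector of class `reaction_presence`.
#' @export
reaction_presence <- function(model, present, provenance = list()) {
  r <- as.integer(model$reaction_ids %in% present)
  names(r) <- model$reaction_ids
  structure(r, provenance = provenance, class = "reaction_presence")
}

#' Reaction-level tINIT extraction
#'
#' MILP that maximizes the summed reaction activity scores of included
#' reactions: positive-score reactions reward inclusion, negative scores
#' penalize it, and every included reaction must carry at least `eps`
#' flux in a single steady-state witness (so the returned subnetwork is
#' flux-consistent by construction). Protected reactions — at minimum
#' the biomass objective — are forced in.
#'
#' @param model a [metabolic_model()].
#' @param ras named numeric reaction scores (e.g. the `ras` column of
#'   [compute_ras()] named by reaction), aligned to the model; missing
#'   reactions default to 0.
#' @param protected reaction identifiers forced into the subnetwork.
#' @param eps activation flux threshold for included reactions.
#' @param gap_tol MILP optimality gap.
#' @return a `reaction_presence` object with `objective` attribute.
#' @export
tinit <- function(model, ras, protected = model$objective_id,
                  eps = 1e-4, gap_tol = 1e-6) {
  n <- length(model$reaction_ids)
  w <- stats::setNames(rep(0, n), model$reaction_ids)
  w[names(ras)[names(ras) %in% model$reaction_ids]] <-
    ras[names(ras) %in% model$reaction_ids]
  pidx <- reaction_index(model, protected)

  # protected reactions must be activatable in the full template
  for (i in seq_along(protected)) {
    f <- fba(model, protected[i], "max")
    g <- fba(model, protected[i], "min")
    ok <- f$status == "optimal" &&
      (f$objective_value >= eps - 1e-9 || g$objective_value <= -(eps - 1e-9))
    if (!ok) stop("protected reaction '", protected[i],
                  "' cannot carry flux in the template model")
  }

  sm <- split_reversible(model)
  Sn <- steady_state_rows(sm)
  ns <- length(sm$reaction_ids)
  map <- sm$split_map
  nv <- ns + n  # [v_split, y]
  rows <- list(); dirs <- character(); rhs <- numeric()
  add_row <- function(row, d, b) {
    rows[[length(rows) + 1L]] <<- row; dirs[length(dirs) + 1L] <<- d
    rhs[length(rhs) + 1L] <<- b
  }
  for (i in seq_len(nrow(Sn))) add_row(c(Sn[i, ], rep(0, n)), "=", 0)
  for (j in seq_len(n)) {
    tot <- numeric(nv)
    tot[map$fwd[j]] <- 1
    if (!is.na(map$rev[j])) tot[map$rev[j]] <- 1
    ubj <- sm$ub[map$fwd[j]] + if (!is.na(map$rev[j])) sm$ub[map$rev[j]] else 0
    up <- tot; up[ns + j] <- -max(ubj, eps)
    add_row(up, "<=", 0)                  # v_f + v_r <= UB * y
    lo <- tot; lo[ns + j] <- -eps
    add_row(lo, ">=", 0)                  # v_f + v_r >= eps * y
  }
  A <- do.call(rbind, rows)
  lbv <- c(sm$lb, rep(0, n))
  ubv <- c(sm$ub, rep(1, n))
  lbv[ns + pidx] <- 1
  obj <- c(rep(0, ns), unname(w))
  res <- solve_milp(obj, A, dirs, rhs, lbv, ubv, binary = ns + seq_len(n),
                    maximize = TRUE, gap_tol = gap_tol)
  if (res$status != "optimal") {
    stop("tINIT MILP infeasible; protected reactions cannot be sustained")
  }
  y <- res$x[ns + seq_len(n)]
  present <- model$reaction_ids[y > 0.5]
  out <- reaction_presence(model, present,
                           provenance = list(algorithm = "tINIT", eps = eps))
  attr(out, "objective") <- res$obj
  attr(out, "witness") <- unsplit_fluxes(sm, res$x[seq_len(ns)])
  out
}

#' Apply a presence vector to a template model
#'
#' Reactions flagged for removal are knocked out (bounds set to zero)
#' rather than structurally deleted, so that gap filling can later
#' re-enable them.
#'
#' @param model template [metabolic_model()].
#' @param r a `reaction_presence` vector aligned to the model.
#' @return the context-specific model.
#' @export
apply_presence <- function(model, r) {
  stopifnot(length(r) == length(model$reaction_ids))
  absent <- model$reaction_ids[as.integer(r) == 0L]
  set_bounds(model, absent, lb = 0, ub = 0)
}

#' Growth checks for a context-specific model
#'
#' @param context_model a [metabolic_model()] (after [apply_presence()]).
#' @param medium optional character vector of medium metabolites; when
#'   given, growth is additionally checked with uptake restricted to the
#'   medium.
#' @param growth_tol minimum biomass flux counted as growth.
#' @return list with `grows`, `growth`, and (when `medium` is supplied)
#'   `grows_on_medium`, `growth_on_medium`. Infeasibility counts as not
#'   growing.
#' @export
check_model <- function(context_model, medium = NULL, growth_tol = 1e-6) {
  f <- fba(context_model)
  grows <- f$status == "optimal" && f$objective_value > growth_tol
  out <- list(grows = grows,
              growth = if (f$status == "optimal") f$objective_value else 0)
  if (!is.null(medium)) {
    fm <- fba(suppressWarnings(apply_medium(context_model, medium)))
    out$grows_on_medium <- fm$status == "optimal" &&
      fm$objective_value > growth_tol
    out$growth_on_medium <- if (fm$status == "optimal") fm$objective_value else 0
  }
  out
}

#' Reconstruction parameter grid
#'
#' Cartesian product of the reconstruction options, filtered by the
#' validity predicate: each thresholding strategy only uses the
#' percentiles it needs (unused ones are fixed to `NA` so no duplicate
#' configurations are emitted), and the two-threshold strategy requires
#' the lower global percentile to be strictly below the upper one.
#' Ordering is deterministic.
#'
#' @param algorithms,strategies,or_fns,and_fns option sets.
#' @param p_gmin,p_gmax,p_local percentile option sets.
#' @return data frame of valid configurations, one row each.
#' @export
parameter_grid <- function(algorithms = c("FASTCORE", "tINIT"),
                           strategies = c("global", "localT1", "localT2"),
                           p_gmin = c(10, 25, 50, 75, 90),
                           p_gmax = c(25, 50, 75, 90),
                           p_local = c(10, 25, 50, 75, 90),
                           or_fns = c("max", "sum"),
                           and_fns = "min") {
  grids <- list()
  for (strat in strategies) {
    g <- switch(strat,
      global = expand.grid(algorithm = algorithms, strategy = strat,
                           p_gmin = NA_real_, p_gmax = p_gmax,
                           p_local = NA_real_, or_fn = or_fns,
                           and_fn = and_fns, stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE),
      localT1 = expand.grid(algorithm = algorithms, strategy = strat,
                            p_gmin = NA_real_, p_gmax = p_gmax,
                            p_local = p_local, or_fn = or_fns,
                            and_fn = and_fns, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE),
      localT2 = {
        gg <- expand.grid(algorithm = algorithms, strategy = strat,
                          p_gmin = p_gmin, p_gmax = p_gmax,
                          p_local = p_local, or_fn = or_fns,
                          and_fn = and_fns, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
        gg[gg$p_gmin < gg$p_gmax, , drop = FALSE]
      },
      stop("unknown strategy: ", strat))
    grids[[strat]] <- g
  }
  out <- do.call(rbind, grids)
  ord <- do.call(order, out[c("algorithm", "strategy", "p_gmin", "p_gmax",
                              "p_local", "or_fn", "and_fn")])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
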