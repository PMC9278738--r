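# Gap filling as a minimum-cardinality MILP: find the smallest set of
# candidate reactions (or medium uptakes) whose activation restores flux
# through a required objective reaction. Binary indicators y_k are coupled
# to fluxes with big-M constraints on the fully split (v >= 0) network.

#' Build a gap-filling problem
#'
#' Two scenarios are supported. `intracellular`: the candidate set K
#' holds the intracellular reactions absent from the presence vector
#' `r`; exchanges are excluded from K and keep their template bounds,
#' while absent non-candidates stay shut. `medium`: the enzyme content
#' is fixed (absent intracellular reactions stay shut) and K holds one
#' uptake candidate per exchange reaction, so the optimal solution is a
#' minimal growth medium. In both, the network is fully split so all
#' fluxes are non-negative and the objective reaction `u` is required to
#' carry at least the activation threshold.
#'
#' @param model template [metabolic_model()].
#' @param r `reaction_presence` vector (or named 0/1 vector) over the
#'   template reactions.
#' @param u objective reaction identifier (usually biomass).
#' @param scenario `"intracellular"` or `"medium"`.
#' @param M big-M constant linking indicators to fluxes; raised
#'   automatically if any bound exceeds it.
#' @param activation_frac activation threshold for `u` as a fraction of
#'   its upper bound.
#' @param lower_coupling also enforce `v_k >= delta * y_k` so selected
#'   candidates must genuinely carry flux.
#' @param open_bound uptake magnitude given to candidate uptakes in the
#'   medium scenario.
#' @return object of class `gapfill_problem`.
#' @export
build_gapfill_problem <- function(model, r, u,
                                  scenario = c("intracellular", "medium"),
                                  M = 1e6, activation_frac = 1e-4,
                                  lower_coupling = TRUE, open_bound = 1000) {
  scenario <- match.arg(scenario)
  stopifnot(length(r) == length(model$reaction_ids))
  rv <- stats::setNames(as.integer(r), model$reaction_ids)
  uidx <- reaction_index(model, u)
  ex <- exchange_reactions(model)
  absent <- model$reaction_ids[rv == 0L]
  work <- model

  if (scenario == "intracellular") {
    # every absent intracellular reaction is a candidate; absent exchanges
    # keep their template bounds (exchanges are never gap-fill targets here)
    candidates <- setdiff(absent, model$reaction_ids[ex])
  } else {
    # enzyme content fixed: absent intracellular reactions stay shut
    shut <- setdiff(absent, model$reaction_ids[ex])
    work <- set_bounds(work, shut, lb = 0, ub = 0)
    # every exchange becomes an uptake candidate
    exids <- model$reaction_ids[ex]
    idx <- reaction_index(work, exids)
    work$lb[idx] <- pmin(work$lb[idx], -abs(open_bound))
    candidates <- exids
  }

  Mbig <- max(M, max(abs(c(work$lb, work$ub))) * 10)
  delta <- activation_frac * max(abs(work$ub[uidx]), 1)
  structure(
    list(model = work, template = model, r = rv, u = u,
         scenario = scenario, K = candidates, M = Mbig, delta = delta,
         lower_coupling = lower_coupling),
    class = "gapfill_problem"
  )
}

#' @export
print.gapfill_problem <- function(x, ...) {
  cat("<gapfill_problem> scenario: ", x$scenario, "; |K| = ", length(x$K),
      "; u = ", x$u, "; M = ", format(x$M), "\n", sep = "")
  invisible(x)
}

# assemble the MILP; extra_rows appends integer cuts for enumeration
gapfill_milp <- function(problem, extra_cuts = list()) {
  model <- problem$model
  sm <- split_reversible(model)
  Sn <- steady_state_rows(sm)
  ns <- length(sm$reaction_ids)
  map <- sm$split_map
  K <- problem$K
  nk <- length(K)
  kidx <- match(K, map$orig)
  nv <- ns + nk
  rows <- list(); dirs <- character(); rhs <- numeric()
  add <- function(row, d, b) {
    rows[[length(rows) + 1L]] <<- row
    dirs[length(dirs) + 1L] <<- d
    rhs[length(rhs) + 1L] <<- b
  }
  for (i in seq_len(nrow(Sn))) add(c(Sn[i, ], rep(0, nk)), "=", 0)

  lbv <- c(sm$lb, rep(0, nk))
  ubv <- c(sm$ub, rep(1, nk))
  # candidate coupling: total candidate flux forced to 0 unless selected
  for (q in seq_len(nk)) {
    j <- kidx[q]
    tot <- numeric(nv)
    if (problem$scenario == "medium") {
      # candidate is the uptake direction only: the split half whose
      # stoichiometry produces the exchanged metabolite
      met <- exchanged_metabolite(problem$model)[reaction_index(problem$model, K[q])]
      fwd <- map$fwd[j]; rev <- map$rev[j]
      upcol <- if (!is.na(rev) &&
                   sm$S[met, rev] > 0) rev
               else if (sm$S[met, fwd] > 0) fwd
               else NA_integer_
      if (is.na(upcol)) next  # exchange cannot import; candidate inert
      tot[upcol] <- 1
      mrow <- sm$ub[upcol]
    } else {
      tot[map$fwd[j]] <- 1
      mrow <- sm$ub[map$fwd[j]]
      if (!is.na(map$rev[j])) {
        tot[map$rev[j]] <- 1
        mrow <- mrow + sm$ub[map$rev[j]]
      }
    }
    # effective big-M: the candidate's own flux capacity bounds the row,
    # so min(M, capacity) is valid and numerically far better conditioned
    up <- tot; up[ns + q] <- -max(min(problem$M, mrow), problem$delta)
    add(up, "<=", 0)
    if (problem$lower_coupling) {
      lo <- tot; lo[ns + q] <- -problem$delta
      add(lo, ">=", 0)
    }
  }
  # non-selected candidates must carry no flux: in the intracellular
  # scenario the template bounds would otherwise let absent reactions run
  # (they are "absent", so they are only available through selection)
  # -> enforced by the big-M row above since flux <= M*y.
  # objective reaction must be active (net forward flux)
  urow <- numeric(nv)
  uj <- reaction_index(model, problem$u)
  urow[map$fwd[uj]] <- 1
  if (!is.na(map$rev[uj])) urow[map$rev[uj]] <- -1
  add(urow, ">=", problem$delta)
  for (cut in extra_cuts) {
    crow <- numeric(nv)
    crow[ns + match(cut, K)] <- 1
    add(crow, "<=", length(cut) - 1)
  }
  A <- do.call(rbind, rows)
  obj <- c(rep(0, ns), rep(1, nk))
  list(A = A, dirs = dirs, rhs = rhs, lb = lbv, ub = ubv, obj = obj,
       ns = ns, nk = nk, sm = sm)
}

#' Solve a gap-filling problem to optimality
#'
#' Minimizes the number of selected candidates subject to steady state,
#' indicator coupling and the activation constraint on the objective
#' reaction. Infeasibility (no candidate set can restore flux) is a
#' regular result, not an error.
#'
#' @param problem a [build_gapfill_problem()] result.
#' @return object of class `gapfill_solution`: list with `status`
#'   (`"optimal"` or `"no_gapfill"`), `selected` (candidate reaction
#'   identifiers), `cardinality`, and `witness` (flux distribution over
#'   the template reactions).
#' @export
efm_gapfill <- function(problem) {
  p <- gapfill_milp(problem)
  res <- solve_milp(p$obj, p$A, p$dirs, p$rhs, p$lb, p$ub,
                    binary = p$ns + seq_len(p$nk))
  if (res$status != "optimal") {
    return(structure(list(status = "no_gapfill", selected = character(),
                          cardinality = NA_integer_, witness = NULL),
                     class = "gapfill_solution"))
  }
  y <- res$x[p$ns + seq_len(p$nk)]
  sel <- problem$K[y > 0.5]
  structure(
    list(status = "optimal", selected = sel, cardinality = length(sel),
         witness = unsplit_fluxes(p$sm, res$x[seq_len(p$ns)])),
    class = "gapfill_solution"
  )
}

#' @export
print.gapfill_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat("<gapfill_solution> no gap-filling set exists\n")
  } else {
    cat("<gapfill_solution> cardinality ", x$cardinality, ": ",
        paste(x$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate alternative gap-filling solutions
#'
#' Repeatedly solves the MILP, excluding each found solution with an
#' integer cut, yielding up to `k` distinct solutions in non-decreasing
#' cardinality (the k-shortest enumeration pattern).
#'
#' @param problem a [build_gapfill_problem()] result.
#' @param k maximum number of solutions.
#' @return list of `gapfill_solution` objects (may be shorter than `k`).
#' @export
enumerate_gapfill_solutions <- function(problem, k) {
  stopifnot(k >= 1)
  out <- list()
  cuts <- list()
  for (i in seq_len(k)) {
    p <- gapfill_milp(problem, extra_cuts = cuts)
    res <- solve_milp(p$obj, p$A, p$dirs, p$rhs, p$lb, p$ub,
                      binary = p$ns + seq_len(p$nk))
    if (res$status != "optimal") break
    y <- res$x[p$ns + seq_len(p$nk)]
    sel <- problem$K[y > 0.5]
    if (!length(sel)) {
      # the empty solution cannot be cut away; it is the unique optimum
      out[[1L]] <- efm_gapfill(problem)
      break
    }
    out[[length(out) + 1L]] <- structure(
      list(status = "optimal", selected = sel, cardinality = length(sel),
           witness = unsplit_fluxes(p$sm, res$x[seq_len(p$ns)])),
      class = "gapfill_solution"
    )
    cuts[[length(cuts) + 1L]] <- sel
  }
  out
}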