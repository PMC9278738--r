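# Steady-state flux simulation: FBA, pFBA, FVA and blocked-reaction
# detection. The steady-state constraint S v = 0 is imposed over
# non-boundary metabolites only (boundary species are buffered).

steady_state_rows <- function(model) {
  model$S[!model$boundary, , drop = FALSE]
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) flux through an objective reaction subject to
#' the steady-state constraint `S v = 0` and the flux bounds — the
#' canonical LP of constraint-based modelling.
#'
#' @param model a [metabolic_model()].
#' @param objective reaction identifier; defaults to the model's biomass
#'   objective.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_distribution`: list with `values` (named flux vector),
#'   `objective_value`, and `status` (`"optimal"` or `"infeasible"`).
#'   Infeasibility is reported, not raised, because downstream callers
#'   (essentiality) must treat it as a non-viable phenotype.
#' @export
fba <- function(model, objective = model$objective_id,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  Sn <- steady_state_rows(model)
  n <- length(model$reaction_ids)
  obj <- numeric(n)
  obj[reaction_index(model, objective)] <- 1
  res <- solve_lp(obj, Sn, rep("=", nrow(Sn)), rep(0, nrow(Sn)),
                  model$lb, model$ub, maximize = (sense == "max"))
  structure(
    list(values = stats::setNames(res$x, model$reaction_ids),
         objective_value = res$obj,
         objective_id = objective,
         status = if (res$status == "optimal") "optimal" else "infeasible"),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status: ", x$status, "; ", x$objective_id,
      " = ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the FBA optimum of the objective is found, then —
#' with the objective flux fixed at that optimum — the total absolute
#' flux `sum(|v|)` is minimized on the reversibly-split model, where the
#' L1 norm is linear. This selects, among alternative optima, the
#' distribution with minimal overall enzyme usage.
#'
#' @inheritParams fba
#' @param fraction_of_optimum fraction of the FBA optimum the objective is
#'   held at during minimization (1 = exact optimum).
#' @return a `flux_distribution` on the original reactions, with an extra
#'   `total_flux` element (`sum(|v|)` of the split solution).
#' @export
pfba <- function(model, objective = model$objective_id,
                 fraction_of_optimum = 1) {
  stage1 <- fba(model, objective, "max")
  if (stage1$status != "optimal") return(stage1)
  sm <- split_reversible(model)
  Sn <- steady_state_rows(sm)
  n <- length(sm$reaction_ids)
  oidx <- reaction_index(model, objective)
  map <- sm$split_map
  orow <- numeric(n)
  orow[map$fwd[oidx]] <- 1
  if (!is.na(map$rev[oidx])) orow[map$rev[oidx]] <- -1
  A <- rbind(Sn, orow)
  dir <- c(rep("=", nrow(Sn)), "=")
  rhs <- c(rep(0, nrow(Sn)), stage1$objective_value * fraction_of_optimum)
  res <- solve_lp(rep(1, n), A, dir, rhs, sm$lb, sm$ub, maximize = FALSE)
  if (res$status != "optimal") {
    # numerically impossible in exact arithmetic; report infeasibility
    return(structure(list(values = stats::setNames(rep(NA_real_, length(model$reaction_ids)),
                                                   model$reaction_ids),
                          objective_value = NA_real_, objective_id = objective,
                          status = "infeasible"),
                     class = "flux_distribution"))
  }
  v <- unsplit_fluxes(sm, res$x)
  structure(
    list(values = v, objective_value = v[[objective]],
         objective_id = objective, status = "optimal",
         total_flux = res$obj),
    class = "flux_distribution"
  )
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject
#' to steady state and bounds, optionally after opening all exchange
#' lower bounds to a configured uptake value.
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction identifiers (default: all).
#' @param open_exchanges open every exchange to uptake before the scan.
#' @param open_bound uptake bound used when opening exchanges.
#' @return data frame with `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$reaction_ids,
                open_exchanges = FALSE, open_bound = -1000) {
  if (open_exchanges) {
    ex <- exchange_reactions(model)
    model$lb[ex] <- pmin(model$lb[ex], open_bound)
  }
  Sn <- steady_state_rows(model)
  n <- length(model$reaction_ids)
  base <- solve_lp(numeric(n), Sn, rep("=", nrow(Sn)), rep(0, nrow(Sn)),
                   model$lb, model$ub)
  if (base$status != "optimal") {
    stop("model is infeasible at steady state; no variability analysis possible")
  }
  idx <- reaction_index(model, reactions)
  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(idx)) {
    obj <- numeric(n); obj[idx[i]] <- 1
    lo <- solve_lp(obj, Sn, rep("=", nrow(Sn)), rep(0, nrow(Sn)),
                   model$lb, model$ub, maximize = FALSE)
    hi <- solve_lp(obj, Sn, rep("=", nrow(Sn)), rep(0, nrow(Sn)),
                   model$lb, model$ub, maximize = TRUE)
    out$min[i] <- lo$obj
    out$max[i] <- hi$obj
  }
  out
}

#' Blocked reactions under open exchange conditions
#'
#' A reaction is blocked when both its minimum and maximum flux are null
#' (within tolerance) with every exchange opened to uptake; blocked
#' reactions can never carry flux and are removed during model
#' preprocessing.
#'
#' @inheritParams fva
#' @param tol absolute flux tolerance below which a flux is null.
#' @return character vector of blocked reaction identifiers.
#' @export
find_blocked_reactions <- function(model, tol = 1e-6, open_exchanges = TRUE,
                                   open_bound = -1000) {
  rng <- fva(model, open_exchanges = open_exchanges, open_bound = open_bound)
  rng$reaction_id[abs(rng$min) <= tol & abs(rng$max) <= tol]
}

#' Steady-state residual of a flux distribution
#'
#' @param model a [metabolic_model()].
#' @param v flux vector along the model's reactions.
#' @return maximum absolute row residual of `S v` over non-boundary
#'   metabolites.
#' @export
steady_state_residual <- function(model, v) {
  Sn <- steady_state_rows(model)
  if (nrow(Sn) == 0L) return(0)
  max(abs(Sn %*% v))
}
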