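#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric matrix with flux
#' bounds, gene-protein-reaction (GPR) rules and a biomass objective. All
#' LP/MILP operations (FBA, FVA, extraction, gap filling) act on this
#' structure. Exchange reactions follow the COBRA convention: a boundary
#' pseudo-reaction with a single nonzero stoichiometric entry, negative
#' flux meaning uptake.
#'
#' @param S stoichiometric matrix, metabolites (rows) x reactions (columns).
#' @param reaction_ids,metabolite_ids unique identifiers matching the
#'   dimensions of `S`.
#' @param lb,ub per-reaction flux bounds (`lb <= ub`), in whatever flux
#'   unit the model uses (mmol/gDW/h for genome-scale models, arbitrary
#'   units in the toy fixtures).
#' @param gpr_rules character vector of Boolean gene rules
#'   (`"g1 and (g2 or g3)"`); `""` for reactions without gene association.
#' @param objective_id identifier of the biomass pseudo-reaction.
#' @param boundary logical per metabolite: SBML `boundaryCondition` species
#'   that buffer exchange reactions and are excluded from the steady-state
#'   constraint.
#' @param subsystems optional per-reaction pathway annotation.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, reaction_ids, metabolite_ids, lb, ub,
                            gpr_rules = NULL, objective_id,
                            boundary = NULL, subsystems = NULL) {
  S <- as.matrix(S)
  n <- ncol(S)
  m <- nrow(S)
  if (is.null(gpr_rules)) gpr_rules <- rep("", n)
  if (is.null(boundary)) boundary <- rep(FALSE, m)
  stopifnot(
    length(reaction_ids) == n, length(metabolite_ids) == m,
    !anyDuplicated(reaction_ids), !anyDuplicated(metabolite_ids),
    length(lb) == n, length(ub) == n, length(gpr_rules) == n,
    length(boundary) == m
  )
  if (any(lb > ub)) stop("lower bound exceeds upper bound for reaction(s): ",
                         paste(reaction_ids[lb > ub], collapse = ", "))
  if (!objective_id %in% reaction_ids) {
    stop("objective reaction '", objective_id, "' not in the model")
  }
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  obj <- structure(
    list(
      S = S,
      reaction_ids = as.character(reaction_ids),
      metabolite_ids = as.character(metabolite_ids),
      lb = as.numeric(lb), ub = as.numeric(ub),
      gpr_rules = as.character(gpr_rules),
      objective_id = objective_id,
      boundary = as.logical(boundary),
      subsystems = if (is.null(subsystems)) rep(NA_character_, n)
                   else as.character(subsystems)
    ),
    class = "metabolic_model"
  )
  obj
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolite_ids), " metabolites x ",
      length(x$reaction_ids), " reactions\n", sep = "")
  cat("  objective: ", x$objective_id, "\n", sep = "")
  cat("  exchanges: ", sum(exchange_reactions(x)), "; genes: ",
      length(model_genes(x)), "\n", sep = "")
  invisible(x)
}

#' Identify exchange reactions
#'
#' A reaction is an exchange if at most one of its stoichiometric entries
#' involves a non-boundary metabolite, i.e. it imports or exports a single
#' species across the system boundary.
#'
#' @param model a [metabolic_model()].
#' @return logical vector along `model$reaction_ids`.
#' @export
exchange_reactions <- function(model) {
  active <- model$S[!model$boundary, , drop = FALSE] != 0
  colSums(active) <= 1L
}

#' Metabolite imported/exported by each exchange reaction
#'
#' @param model a [metabolic_model()].
#' @return character vector along reactions; `NA` for non-exchanges.
#' @export
exchanged_metabolite <- function(model) {
  ex <- exchange_reactions(model)
  mets <- model$metabolite_ids[!model$boundary]
  Sn <- model$S[!model$boundary, , drop = FALSE]
  out <- rep(NA_character_, length(model$reaction_ids))
  for (j in which(ex)) {
    nz <- which(Sn[, j] != 0)
    if (length(nz) == 1L) out[j] <- mets[nz]
  }
  names(out) <- model$reaction_ids
  out
}

#' Genes registered in a model's GPR rules
#'
#' @param model a [metabolic_model()].
#' @return sorted character vector of gene identifiers.
#' @export
model_genes <- function(model) {
  g <- unique(unlist(lapply(model$gpr_rules, gpr_genes)))
  sort(g)
}

reaction_index <- function(model, ids) {
  idx <- match(ids, model$reaction_ids)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Remove boundary metabolites
#'
#' Boundary species (SBML `boundaryCondition = true`) exist only to
#' mass-balance exchange reactions; they are not subject to the
#' steady-state constraint and are stripped before reconstruction or
#' simulation. Reactions are never deleted; exchanges simply become
#' single-sided.
#'
#' @param model a [metabolic_model()].
#' @return the model without boundary metabolite rows.
#' @export
remove_boundary_metabolites <- function(model) {
  if (!any(model$boundary)) return(model)
  keep <- !model$boundary
  metabolic_model(
    S = model$S[keep, , drop = FALSE],
    reaction_ids = model$reaction_ids,
    metabolite_ids = model$metabolite_ids[keep],
    lb = model$lb, ub = model$ub,
    gpr_rules = model$gpr_rules,
    objective_id = model$objective_id,
    boundary = rep(FALSE, sum(keep)),
    subsystems = model$subsystems
  )
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound becomes a forward/reverse
#' pair with mirrored stoichiometry so that all fluxes are non-negative —
#' the form required by L1-minimizing pFBA and by the gap-filling MILP,
#' whose constraints assume `v >= 0`. The mapping between original and
#' split reactions is retained so fluxes can be recombined
#' (`forward - reverse`).
#'
#' @param model a [metabolic_model()].
#' @return a `metabolic_model` with an additional `split_map` data frame
#'   (`orig`, `fwd`, `rev`; `rev` is `NA` for reactions left unsplit).
#' @export
split_reversible <- function(model) {
  n <- length(model$reaction_ids)
  cols <- list(); ids <- character(); lb <- numeric(); ub <- numeric()
  gpr <- character(); subs <- character()
  map <- data.frame(orig = model$reaction_ids, fwd = NA_integer_,
                    rev = NA_integer_, stringsAsFactors = FALSE)
  k <- 0L
  for (j in seq_len(n)) {
    k <- k + 1L
    cols[[k]] <- model$S[, j]
    ids[k] <- model$reaction_ids[j]
    lb[k] <- max(model$lb[j], 0)
    ub[k] <- max(model$ub[j], 0)
    gpr[k] <- model$gpr_rules[j]
    subs[k] <- model$subsystems[j]
    map$fwd[j] <- k
    if (model$lb[j] < 0) {
      k <- k + 1L
      cols[[k]] <- -model$S[, j]
      ids[k] <- paste0(model$reaction_ids[j], "__rev")
      lb[k] <- max(-model$ub[j], 0)
      ub[k] <- -model$lb[j]
      gpr[k] <- model$gpr_rules[j]
      subs[k] <- model$subsystems[j]
      map$rev[j] <- k
    }
  }
  Ssp <- do.call(cbind, cols)
  out <- metabolic_model(
    S = Ssp, reaction_ids = ids, metabolite_ids = model$metabolite_ids,
    lb = lb, ub = ub, gpr_rules = gpr,
    objective_id = model$objective_id,
    boundary = model$boundary, subsystems = subs
  )
  out$split_map <- map
  out
}

#' Recombine a split-model flux vector into original-reaction fluxes
#'
#' @param split_model result of [split_reversible()].
#' @param v flux vector on the split model.
#' @return flux vector along the original reactions (`forward - reverse`).
#' @export
unsplit_fluxes <- function(split_model, v) {
  map <- split_model$split_map
  out <- v[map$fwd]
  has_rev <- !is.na(map$rev)
  out[has_rev] <- out[has_rev] - v[map$rev[has_rev]]
  names(out) <- map$orig
  out
}

#' Constrain uptake to a growth medium
#'
#' Exchange reactions whose metabolite is not in the medium are restricted
#' to non-negative flux (secretion only), so only medium metabolites can
#' be consumed. Exchanges for medium metabolites keep their bounds.
#'
#' @param model a [metabolic_model()].
#' @param medium_metabolites character vector of metabolite identifiers
#'   allowed to be taken up. Names not matching any exchanged metabolite
#'   trigger a warning (media lists are often partial), not an error.
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium_metabolites) {
  exmet <- exchanged_metabolite(model)
  unknown <- setdiff(medium_metabolites, exmet[!is.na(exmet)])
  if (length(unknown)) {
    warning("medium metabolite(s) not found on any exchange: ",
            paste(unknown, collapse = ", "))
  }
  shut <- !is.na(exmet) & !(exmet %in% medium_metabolites)
  model$lb[shut] <- pmax(model$lb[shut], 0)
  model
}

#' Set per-reaction flux bounds
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction identifiers.
#' @param lb,ub replacement bounds (recycled).
#' @return the updated model.
#' @export
set_bounds <- function(model, reactions, lb = NULL, ub = NULL) {
  idx <- reaction_index(model, reactions)
  if (!is.null(lb)) model$lb[idx] <- lb
  if (!is.null(ub)) model$ub[idx] <- ub
  if (any(model$lb[idx] > model$ub[idx])) stop("lb > ub after update")
  model
}
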