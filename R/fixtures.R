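# Desk-scale fixtures: toy metabolic networks with known ground truth,
# synthetic TPM matrices with planted structure, and exhaustive
# enumeration oracles. These stand in for genome-scale models and
# RNA-seq compendia so that every pipeline stage is testable locally.

#' Generate a toy metabolic model with known ground truth
#'
#' Each topology encodes a property the pipeline must get right:
#' `chain` (linear pathway, every internal gene essential), `diamond`
#' (2- vs 3-reaction alternative routes, pFBA must take the short one),
#' `dead_end` (a structurally blocked branch), `isozyme` (an `or` backup
#' and an `and` complex), `parallel_paths` (two gene-tagged routes for
#' score-based extraction), `minimal_medium` (growth requires one of two
#' importable substrates), and `boundary` (explicit SBML boundary
#' species on the exchanges). Ground truth (blocked reactions, essential
#' genes, minimal subnetworks) is attached as the `ground_truth`
#' attribute.
#'
#' @param topology one of `"chain"`, `"diamond"`, `"dead_end"`,
#'   `"isozyme"`, `"parallel_paths"`, `"minimal_medium"`, `"boundary"`.
#' @param chain_len number of reactions for `"chain"` (>= 3).
#' @param bound flux bound used throughout (default 10).
#' @return a [metabolic_model()] with a `ground_truth` attribute.
#' @export
make_toy_model <- function(topology = c("chain", "diamond", "dead_end",
                                        "isozyme", "parallel_paths",
                                        "minimal_medium", "boundary"),
                           chain_len = 3, bound = 10) {
  topology <- match.arg(topology)
  b <- bound
  gt <- list()
  if (topology == "chain") {
    if (chain_len < 3) stop("chain topology needs at least 3 reactions")
    nmet <- chain_len - 1L
    mets <- paste0("M", seq_len(nmet))
    rxns <- c("R_src", if (chain_len > 2) paste0("R", seq_len(chain_len - 2L)),
              "biomass")
    S <- matrix(0, nmet, chain_len, dimnames = list(mets, rxns))
    S[1, 1] <- 1
    for (j in seq_len(chain_len - 2L)) {
      S[j, j + 1L] <- -1
      S[j + 1L, j + 1L] <- 1
    }
    S[nmet, chain_len] <- -1
    gpr <- c("", paste0("g", seq_len(chain_len - 2L)), "")
    mdl <- metabolic_model(S, rxns, mets, rep(0, chain_len), rep(b, chain_len),
                           gpr, "biomass")
    gt$blocked <- character()
    gt$essential_genes <- paste0("g", seq_len(chain_len - 2L))
    gt$max_growth <- b
  } else if (topology == "diamond") {
    mets <- c("A", "P1", "Q1", "Q2", "Z")
    rxns <- c("R_src", "S1", "S2", "L1", "L2", "L3", "biomass")
    S <- matrix(0, 5, 7, dimnames = list(mets, rxns))
    S["A", "R_src"] <- 1
    S["A", "S1"] <- -1; S["P1", "S1"] <- 1
    S["P1", "S2"] <- -1; S["Z", "S2"] <- 1
    S["A", "L1"] <- -1; S["Q1", "L1"] <- 1
    S["Q1", "L2"] <- -1; S["Q2", "L2"] <- 1
    S["Q2", "L3"] <- -1; S["Z", "L3"] <- 1
    S["Z", "biomass"] <- -1
    gpr <- c("", "gS1", "gS2", "gL1", "gL2", "gL3", "")
    mdl <- metabolic_model(S, rxns, mets, rep(0, 7), rep(b, 7), gpr, "biomass")
    gt$short_path <- c("S1", "S2")
    gt$long_path <- c("L1", "L2", "L3")
    gt$blocked <- character()
    gt$essential_genes <- character()  # either path sustains growth
    gt$max_growth <- b
  } else if (topology == "dead_end") {
    mets <- c("M1", "M2", "X")
    rxns <- c("R_src", "R1", "biomass", "R_dead")
    S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
    S["M1", "R_src"] <- 1
    S["M1", "R1"] <- -1; S["M2", "R1"] <- 1
    S["M2", "biomass"] <- -1
    S["M1", "R_dead"] <- -1; S["X", "R_dead"] <- 1
    mdl <- metabolic_model(S, rxns, mets, rep(0, 4), rep(b, 4),
                           c("", "g1", "", "gd"), "biomass")
    gt$blocked <- "R_dead"
    gt$essential_genes <- "g1"
    gt$max_growth <- b
  } else if (topology == "isozyme") {
    mets <- c("M1", "M2", "M3")
    rxns <- c("R_src", "RA", "RB", "biomass")
    S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
    S["M1", "R_src"] <- 1
    S["M1", "RA"] <- -1; S["M2", "RA"] <- 1
    S["M2", "RB"] <- -1; S["M3", "RB"] <- 1
    S["M3", "biomass"] <- -1
    mdl <- metabolic_model(S, rxns, mets, rep(0, 4), rep(b, 4),
                           c("", "g1 or g2", "g3 and g4", ""), "biomass")
    gt$blocked <- character()
    gt$essential_genes <- c("g3", "g4")      # complex subunits
    gt$nonessential_genes <- c("g1", "g2")   # isozyme backup
    gt$max_growth <- b
  } else if (topology == "parallel_paths") {
    mets <- c("A", "B", "C", "Z")
    rxns <- c("R_src", "P1", "P2", "N1", "N2", "biomass")
    S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
    S["A", "R_src"] <- 1
    S["A", "P1"] <- -1; S["B", "P1"] <- 1
    S["B", "P2"] <- -1; S["Z", "P2"] <- 1
    S["A", "N1"] <- -1; S["C", "N1"] <- 1
    S["C", "N2"] <- -1; S["Z", "N2"] <- 1
    S["Z", "biomass"] <- -1
    mdl <- metabolic_model(S, rxns, mets, rep(0, 6), rep(b, 6),
                           c("", "gP1", "gP2", "gN1", "gN2", ""), "biomass")
    gt$path_pos <- c("P1", "P2")
    gt$path_neg <- c("N1", "N2")
    gt$blocked <- character()
    gt$max_growth <- b
  } else if (topology == "minimal_medium") {
    mets <- c("X", "Y", "P", "W")
    rxns <- c("EX_X", "EX_Y", "R1", "R2", "EX_W", "biomass")
    S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
    S["X", "EX_X"] <- -1
    S["Y", "EX_Y"] <- -1
    S["X", "R1"] <- -1; S["P", "R1"] <- 1
    S["Y", "R2"] <- -1; S["W", "R2"] <- 1
    S["W", "EX_W"] <- -1
    S["P", "biomass"] <- -1
    mdl <- metabolic_model(S, rxns, mets,
                           lb = c(-b, -b, 0, 0, 0, 0),
                           ub = c(b, b, b, b, b, b),
                           gpr_rules = c("", "", "g1", "g2", "", ""),
                           objective_id = "biomass")
    gt$growth_substrate <- "X"
    gt$inert_substrate <- "Y"
    gt$blocked <- character()
    gt$max_growth <- b
  } else { # boundary
    mets <- c("B_in", "M1", "M2", "B_out")
    rxns <- c("R_src", "R1", "biomass")
    S <- matrix(0, 4, 3, dimnames = list(mets, rxns))
    S["B_in", "R_src"] <- -1; S["M1", "R_src"] <- 1
    S["M1", "R1"] <- -1; S["M2", "R1"] <- 1
    S["M2", "biomass"] <- -1; S["B_out", "biomass"] <- 1
    mdl <- metabolic_model(S, rxns, mets, rep(0, 3), rep(b, 3),
                           c("", "g1", ""), "biomass",
                           boundary = c(TRUE, FALSE, FALSE, TRUE))
    gt$boundary_metabolites <- c("B_in", "B_out")
    gt$blocked <- character()
    gt$essential_genes <- "g1"
    gt$max_growth <- b
  }
  attr(mdl, "ground_truth") <- gt
  mdl
}

#' Random feasible toy network for property sweeps
#'
#' A source-to-biomass chain backbone with extra random internal
#' reactions, a random subset of which is reversible. Always able to
#' grow; used for invariance properties (splitting, pFBA parsimony),
#' not for ground-truth assertions.
#'
#' @param seed integer seed (generation is seed-deterministic and does
#'   not disturb the caller's RNG state).
#' @param n_extra number of extra random internal reactions.
#' @param chain_len backbone length (>= 3).
#' @param bound flux bound magnitude.
#' @return a [metabolic_model()].
#' @export
random_toy_model <- function(seed, n_extra = 4, chain_len = 4, bound = 10) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  base <- make_toy_model("chain", chain_len = chain_len, bound = bound)
  S <- base$S
  mets <- rownames(S)
  lb <- base$lb; ub <- base$ub; ids <- colnames(S); gpr <- base$gpr_rules
  for (e in seq_len(n_extra)) {
    pair <- sample(length(mets), 2)
    col <- numeric(length(mets))
    col[pair[1]] <- -1; col[pair[2]] <- 1
    S <- cbind(S, col)
    ids <- c(ids, paste0("RX", e))
    rev <- stats::runif(1) < 0.5
    lb <- c(lb, if (rev) -bound else 0)
    ub <- c(ub, bound)
    gpr <- c(gpr, paste0("gx", e))
  }
  metabolic_model(S, ids, mets, lb, ub, gpr, "biomass")
}

#' Synthetic TPM expression matrix with planted structure
#'
#' Log-normal TPM values with an optional fraction of dropout zeros and
#' optional planted "active"/"inactive" transcript sets whose means are
#' separated by a configurable fold change from the background. Dropout
#' is confined to background transcripts so the planted truth stays
#' recoverable by thresholding. Planted memberships are recorded in the
#' `planted` attribute.
#'
#' @param n_transcripts,n_samples matrix dimensions.
#' @param seed integer seed; generation is seed-deterministic.
#' @param zero_fraction expected fraction of zero entries among
#'   background transcripts.
#' @param n_active,n_inactive sizes of the planted sets.
#' @param separation fold change between planted-active (x) /
#'   planted-inactive (1/x) means and the background mean.
#' @param base_tpm background mean TPM (log-normal location).
#' @param sdlog log-scale standard deviation.
#' @return numeric matrix (transcripts x samples) with dimnames and a
#'   `planted` attribute (`active`, `inactive` transcript ids).
#' @export
synth_expression <- function(n_transcripts, n_samples, seed,
                             zero_fraction = 0, n_active = 0,
                             n_inactive = 0, separation = 8,
                             base_tpm = 10, sdlog = 0.5) {
  stopifnot(n_active + n_inactive <= n_transcripts, n_samples >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  tx <- paste0("t", seq_len(n_transcripts))
  active <- if (n_active) tx[seq_len(n_active)] else character()
  inactive <- if (n_inactive) tx[n_active + seq_len(n_inactive)] else character()
  meanlog <- rep(log(base_tpm), n_transcripts)
  meanlog[tx %in% active] <- log(base_tpm * separation)
  meanlog[tx %in% inactive] <- log(base_tpm / separation)
  X <- matrix(stats::rlnorm(n_transcripts * n_samples,
                            meanlog = rep(meanlog, n_samples),
                            sdlog = sdlog),
              nrow = n_transcripts,
              dimnames = list(tx, paste0("s", seq_len(n_samples))))
  if (zero_fraction > 0) {
    bg <- !(tx %in% c(active, inactive))
    drop <- matrix(stats::runif(n_transcripts * n_samples) < zero_fraction,
                   nrow = n_transcripts)
    drop[!bg, ] <- FALSE
    X[drop] <- 0
  }
  attr(X, "planted") <- list(active = active, inactive = inactive)
  X
}

# ---- enumeration oracles ---------------------------------------------------

# feasibility: can every reaction of `active` carry >= eps flux (in some
# direction) within the subnetwork where all other reactions are shut?
subnetwork_consistent <- function(model, active, eps) {
  shut <- setdiff(model$reaction_ids, active)
  m2 <- set_bounds(model, shut, lb = 0, ub = 0)
  rng <- fva(m2, reactions = active)
  all(rng$max >= eps - 1e-9 | rng$min <= -(eps - 1e-9))
}

#' Brute-force minimum consistent supersets of a core set
#'
#' Enumerates all reaction subsets containing the core, in increasing
#' cardinality, and returns the smallest flux-consistent ones — the
#' independent oracle for FASTCORE on networks of up to about a dozen
#' reactions.
#'
#' @param model a [metabolic_model()].
#' @param core character vector of core reaction identifiers.
#' @param eps flux activation threshold.
#' @return list of character vectors (all minimum-cardinality solutions).
#' @export
brute_force_min_consistent_superset <- function(model, core, eps = 1e-4) {
  others <- setdiff(model$reaction_ids, core)
  if (length(others) > 15) stop("oracle limited to small networks")
  for (extra in 0:length(others)) {
    sols <- list()
    combs <- if (extra == 0) list(character()) else
      utils::combn(others, extra, simplify = FALSE)
    for (add in combs) {
      act <- c(core, add)
      if (subnetwork_consistent(model, act, eps)) {
        sols[[length(sols) + 1L]] <- sort(act)
      }
    }
    if (length(sols)) return(sols)
  }
  list()
}

#' Brute-force minimal gap-filling sets
#'
#' Enumerates subsets of the candidate set `K` in increasing cardinality
#' and returns every minimum-cardinality subset whose activation lets the
#' objective reaction `u` carry at least the activation threshold —
#' the independent oracle for the gap-filling MILP.
#'
#' @param model template [metabolic_model()].
#' @param r named logical/0-1 vector of reaction presence.
#' @param u objective reaction identifier.
#' @param K character vector of candidate reaction identifiers.
#' @param delta activation flux threshold for `u`.
#' @param medium_scenario if `TRUE`, candidates are exchange reactions and
#'   non-selected exchanges are closed to uptake (intracellular absences
#'   stay shut); otherwise candidates are intracellular reactions.
#' @return list with `solutions` (list of character vectors, possibly
#'   empty) and `cardinality`.
#' @export
brute_force_min_gapfill <- function(model, r, u, K, delta = 1e-4,
                                    medium_scenario = FALSE) {
  if (length(K) > 15) stop("oracle limited to |K| <= 15")
  absent <- names(r)[!as.logical(r)]
  feasible_with <- function(sel) {
    m2 <- model
    if (medium_scenario) {
      m2 <- set_bounds(m2, setdiff(absent, model$reaction_ids[exchange_reactions(model)]),
                       lb = 0, ub = 0)
      shut_up <- setdiff(K, sel)
      idx <- reaction_index(m2, shut_up)
      m2$lb[idx] <- pmax(m2$lb[idx], 0)
      open <- reaction_index(m2, sel)
      m2$lb[open] <- pmin(m2$lb[open], -1000)
    } else {
      shut <- setdiff(absent, sel)
      m2 <- set_bounds(m2, shut, lb = 0, ub = 0)
    }
    f <- fba(m2, u, "max")
    f$status == "optimal" && f$objective_value >= delta - 1e-9
  }
  for (card in 0:length(K)) {
    sols <- list()
    combs <- if (card == 0) list(character()) else
      utils::combn(K, card, simplify = FALSE)
    for (sel in combs) {
      if (feasible_with(sel)) sols[[length(sols) + 1L]] <- sort(sel)
    }
    if (length(sols)) return(list(solutions = sols, cardinality = card))
  }
  list(solutions = list(), cardinality = NA_integer_)
}

#' Brute-force optimum of the reaction-level tINIT objective
#'
#' Enumerates every reaction subset containing the protected reactions and
#' scores feasible ones (a single steady-state flux vector must carry at
#' least `eps` through every included reaction) by the summed reaction
#' activity scores — the independent oracle for the tINIT MILP.
#'
#' @param model a [metabolic_model()].
#' @param weights named numeric reaction scores.
#' @param protected reaction identifiers forced into the subnetwork.
#' @param eps activation flux threshold.
#' @return list with `objective` (best score) and `subnetwork`.
#' @export
brute_force_tinit <- function(model, weights, protected, eps = 1e-4) {
  free <- setdiff(model$reaction_ids, protected)
  if (length(free) > 12) stop("oracle limited to small networks")
  sm <- split_reversible(model)
  Sn <- steady_state_rows(sm)
  best <- list(objective = -Inf, subnetwork = NULL)
  for (card in 0:length(free)) {
    combs <- if (card == 0) list(character()) else
      utils::combn(free, card, simplify = FALSE)
    for (add in combs) {
      act <- c(protected, add)
      score <- sum(weights[act])
      if (score <= best$objective) next
      # feasibility: one witness with every included reaction active
      idx <- match(act, sm$split_map$orig)
      lb2 <- sm$lb; ub2 <- sm$ub
      shut <- setdiff(model$reaction_ids, act)
      sidx <- match(shut, sm$split_map$orig)
      for (i in sidx) {
        ub2[sm$split_map$fwd[i]] <- 0
        if (!is.na(sm$split_map$rev[i])) ub2[sm$split_map$rev[i]] <- 0
      }
      extra <- matrix(0, length(idx), length(sm$reaction_ids))
      for (q in seq_along(idx)) {
        extra[q, sm$split_map$fwd[idx[q]]] <- 1
        if (!is.na(sm$split_map$rev[idx[q]])) {
          extra[q, sm$split_map$rev[idx[q]]] <- 1
        }
      }
      A <- rbind(Sn, extra)
      dir <- c(rep("=", nrow(Sn)), rep(">=", nrow(extra)))
      rhs <- c(rep(0, nrow(Sn)), rep(eps, nrow(extra)))
      f <- solve_lp(numeric(length(sm$reaction_ids)), A, dir, rhs, lb2, ub2)
      if (f$status == "optimal") {
        best <- list(objective = score, subnetwork = sort(act))
      }
    }
  }
  best
}
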