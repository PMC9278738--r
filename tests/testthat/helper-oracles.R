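# Shared oracle helpers. These deliberately construct their LPs and truth
# tables naively, independent of the package's code paths, so agreement
# with the implementation is informative.

# per-reaction two-LP flux range built directly from the model matrices
naive_flux_range <- function(model, j, open_exchanges = TRUE,
                             open_bound = -1000) {
  lb <- model$lb; ub <- model$ub
  if (open_exchanges) {
    ex <- exchange_reactions(model)
    lb[ex] <- pmin(lb[ex], open_bound)
  }
  Sn <- model$S[!model$boundary, , drop = FALSE]
  obj <- numeric(ncol(Sn)); obj[j] <- 1
  lo <- solve_lp(obj, Sn, rep("=", nrow(Sn)), rep(0, nrow(Sn)), lb, ub)
  hi <- solve_lp(obj, Sn, rep("=", nrow(Sn)), rep(0, nrow(Sn)), lb, ub,
                 maximize = TRUE)
  c(min = lo$obj, max = hi$obj)
}

naive_blocked <- function(model, tol = 1e-6) {
  hits <- vapply(seq_along(model$reaction_ids), function(j) {
    r <- naive_flux_range(model, j)
    abs(r["min"]) <= tol && abs(r["max"]) <= tol
  }, logical(1))
  model$reaction_ids[hits]
}

# exhaustive Boolean evaluation of a GPR string by brute substitution
truth_table_eval <- function(rule_string, states) {
  expr <- gsub("\\band\\b", "&&", rule_string, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  for (g in names(states)) {
    expr <- gsub(paste0("\\b", g, "\\b"), if (states[[g]]) "TRUE" else "FALSE",
                 expr)
  }
  eval(parse(text = expr))
}

random_gpr_rule <- function(genes, depth = 2) {
  if (depth == 0 || (length(genes) == 1) || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  left <- random_gpr_rule(genes, depth - 1)
  right <- random_gpr_rule(genes, depth - 1)
  paste0("(", left, " ", op, " ", right, ")")
}
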