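# Gene-protein-reaction rules: Boolean expressions over gene identifiers
# that state which gene products (complexes = AND, isozymes = OR) catalyse
# a reaction. Parsed once into an expression tree that is evaluated either
# with Boolean semantics (gene knockouts) or numerically (activity scores).

#' Parse a gene-protein-reaction rule
#'
#' Accepts rules over gene identifiers with `and` / `or` operators
#' (case-insensitive; `&`/`&&` and `|`/`||` also accepted) and
#' parentheses. `or` binds weaker than `and`, the usual GPR convention.
#'
#' @param rule rule string; empty/whitespace rules yield `NULL` (no GPR).
#' @return an object of class `gpr_rule` (expression tree plus original
#'   string), or `NULL` for an empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st, rule)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error in '", rule, "': unexpected token '",
         st$toks[st$pos], "' at position ", st$pos)
  }
  structure(list(tree = tree, rule = rule), class = "gpr_rule")
}

gpr_tokenize <- function(rule) {
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st, rule) {
  args <- list(gpr_parse_and(st, rule))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st, rule)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, rule) {
  args <- list(gpr_parse_atom(st, rule))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st, rule)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st, rule) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("GPR parse error in '", rule, "': unexpected end of rule")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st, rule)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error in '", rule, "': unbalanced parentheses at position ",
           st$pos)
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("GPR parse error in '", rule, "': unexpected token '", tok,
         "' at position ", st$pos)
  }
  st$pos <- st$pos + 1L
  list(gene = tok)
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", x$rule, "\n", sep = "")
  invisible(x)
}

#' Genes mentioned in a GPR rule
#'
#' @param rule a `gpr_rule`, rule string, or `NULL`.
#' @return character vector of gene identifiers (possibly empty).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(character())
  walk <- function(node) {
    if (!is.null(node$gene)) return(node$gene)
    unlist(lapply(node$args, walk))
  }
  unique(walk(rule$tree))
}

#' Evaluate a GPR rule with Boolean gene states
#'
#' @param rule a `gpr_rule` or rule string.
#' @param states named logical vector of gene states; genes missing from
#'   `states` default to `default`.
#' @param default state for unlisted genes (active, the usual knockout
#'   convention).
#' @return logical.
#' @export
eval_gpr <- function(rule, states, default = TRUE) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(NA)
  walk <- function(node) {
    if (!is.null(node$gene)) {
      s <- states[node$gene]
      if (is.na(s)) s <- default
      return(as.logical(s))
    }
    vals <- vapply(node$args, walk, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  walk(rule$tree)
}

#' Numeric reaction activity score from a GPR rule
#'
#' Replaces Boolean operators with arithmetic: `and` becomes the minimum
#' (an enzyme is limited by its least-expressed subunit), `or` becomes
#' either the maximum or the sum of its operands (isozymes compete or
#' add up). Evaluation is direct on the expression tree, without DNF
#' expansion.
#'
#' @param rule a `gpr_rule`, rule string, or `NULL`.
#' @param tas named numeric vector of transcript activity scores.
#' @param or_fn `"max"` or `"sum"`.
#' @param and_fn `"min"` (default) or `"max"`.
#' @param missing_value score substituted for genes absent from `tas`
#'   (default 0, the neutral activity score); substitutions are recorded
#'   in the `missing_genes` attribute.
#' @return numeric score; `NA` with attribute for empty rules.
#' @export
reaction_score <- function(rule, tas, or_fn = c("max", "sum"),
                           and_fn = c("min", "max"), missing_value = 0) {
  or_fn <- match.arg(or_fn)
  and_fn <- match.arg(and_fn)
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(NA_real_)
  missing_genes <- character()
  walk <- function(node) {
    if (!is.null(node$gene)) {
      v <- tas[node$gene]
      if (is.na(v)) {
        missing_genes <<- c(missing_genes, node$gene)
        v <- missing_value
      }
      return(as.numeric(v))
    }
    vals <- vapply(node$args, walk, numeric(1))
    if (node$op == "and") {
      if (and_fn == "min") min(vals) else max(vals)
    } else {
      if (or_fn == "max") max(vals) else sum(vals)
    }
  }
  out <- walk(rule$tree)
  attr(out, "missing_genes") <- unique(missing_genes)
  out
}

#' Reaction activity scores for a whole model
#'
#' @param model a [metabolic_model()].
#' @param tas named numeric vector of transcript activity scores for one
#'   sample.
#' @inheritParams reaction_score
#' @return data frame with `reaction_id`, `ras`, and `has_gpr`; reactions
#'   without a GPR carry the configured default score and are flagged.
#' @param default_score score assigned to reactions without a GPR.
#' @export
compute_ras <- function(model, tas, or_fn = c("max", "sum"),
                        and_fn = c("min", "max"), default_score = 0) {
  or_fn <- match.arg(or_fn)
  and_fn <- match.arg(and_fn)
  n <- length(model$reaction_ids)
  ras <- numeric(n)
  has_gpr <- nzchar(trimws(model$gpr_rules))
  for (j in seq_len(n)) {
    if (has_gpr[j]) {
      ras[j] <- as.numeric(reaction_score(model$gpr_rules[j], tas,
                                          or_fn = or_fn, and_fn = and_fn))
    } else {
      ras[j] <- default_score
    }
  }
  data.frame(reaction_id = model$reaction_ids, ras = ras,
             has_gpr = has_gpr, stringsAsFactors = FALSE)
}

#' Core reaction set for FASTCORE
#'
#' Core reactions are those with a strictly positive reaction activity
#' score; reactions without a GPR are never part of the core.
#'
#' @param ras a data frame from [compute_ras()].
#' @return character vector of core reaction identifiers.
#' @export
core_set <- function(ras) {
  ras$reaction_id[ras$has_gpr & ras$ras > 0]
}

#' Reactions disabled by a single-gene knockout
#'
#' Evaluates each reaction's GPR with every gene active except the
#' knocked-out one; reactions whose rule evaluates false lose their
#' catalyst and are disabled. Reactions without a GPR are never affected.
#'
#' @param gene gene identifier.
#' @param model a [metabolic_model()].
#' @return character vector of affected reaction identifiers; unknown
#'   genes yield an empty set with a warning (essentiality screens
#'   routinely include non-metabolic genes).
#' @export
knockout_affected_reactions <- function(gene, model) {
  genes <- model_genes(model)
  if (!gene %in% genes) {
    warning("gene '", gene, "' not present in any GPR rule")
    return(character())
  }
  states <- stats::setNames(FALSE, gene)
  has_gpr <- nzchar(trimws(model$gpr_rules))
  hit <- vapply(seq_along(model$reaction_ids), function(j) {
    if (!has_gpr[j]) return(FALSE)
    if (!gene %in% gpr_genes(model$gpr_rules[j])) return(FALSE)
    isFALSE(eval_gpr(model$gpr_rules[j], states, default = TRUE))
  }, logical(1))
  model$reaction_ids[hit]
}
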