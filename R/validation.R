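# Model validation: in-silico gene essentiality against CRISPR screens,
# multiclass Matthews correlation, flux-activity discretization, and
# parameter-importance regression over reconstruction grids.

#' In-silico single-gene essentiality screen
#'
#' For each gene, the reactions whose GPR fails without it are knocked
#' out (bounds set to zero), biomass is re-optimized with FBA, and the
#' knockout is called lethal when the mutant/wild-type biomass ratio
#' falls below the lethality fraction (0.1% of wild type by default) or
#' the mutant problem is infeasible. Bounds are fully restored between
#' genes.
#'
#' @param context_model a growing [metabolic_model()].
#' @param genes gene identifiers to screen; genes absent from every GPR
#'   disable nothing and are non-essential.
#' @param lethality_fraction mutant/wild-type growth ratio below which a
#'   knockout is lethal.
#' @return data frame with `gene`, `n_reactions_disabled`,
#'   `mutant_growth`, `growth_ratio`, `essential`.
#' @export
essentiality_screen <- function(context_model, genes,
                                lethality_fraction = 0.001) {
  wt <- fba(context_model)
  if (wt$status != "optimal" || wt$objective_value <= 1e-9) {
    stop("wild-type model does not grow; lethality is undefined ",
         "(run check_model() before screening)")
  }
  wt_growth <- wt$objective_value
  known <- model_genes(context_model)
  out <- data.frame(gene = genes, n_reactions_disabled = 0L,
                    mutant_growth = NA_real_, growth_ratio = NA_real_,
                    essential = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    affected <- if (g %in% known) {
      knockout_affected_reactions(g, context_model)
    } else character()
    out$n_reactions_disabled[i] <- length(affected)
    if (!length(affected)) {
      out$mutant_growth[i] <- wt_growth
      out$growth_ratio[i] <- 1
      next
    }
    mut <- set_bounds(context_model, affected, lb = 0, ub = 0)
    f <- fba(mut)
    if (f$status != "optimal") {
      out$mutant_growth[i] <- 0
      out$growth_ratio[i] <- 0
      out$essential[i] <- TRUE
    } else {
      out$mutant_growth[i] <- f$objective_value
      out$growth_ratio[i] <- f$objective_value / wt_growth
      out$essential[i] <- out$growth_ratio[i] < lethality_fraction
    }
  }
  attr(out, "wild_type_growth") <- wt_growth
  attr(out, "lethality_fraction") <- lethality_fraction
  out
}

#' Discretize CERES dependency scores into essentiality classes
#'
#' CERES scores estimate the fitness effect of knocking a gene out; more
#' negative means more essential. A gene is experimentally essential
#' when its score is at or below the chosen threshold. Missing scores
#' drop the gene (screens rarely cover everything).
#'
#' @param scores named numeric CERES scores.
#' @param threshold essentiality cutoff, typically from
#'   [ceres_threshold_grid()].
#' @return named logical vector (`TRUE` = essential), `NA`-score genes
#'   removed.
#' @export
discretize_ceres <- function(scores, threshold) {
  keep <- !is.na(scores)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " gene(s) without a CERES score")
  }
  scores[keep] <= threshold
}

#' Default grid of CERES essentiality thresholds
#'
#' Five thresholds evenly distributed across \[-1.5, -0.5\].
#'
#' @return numeric vector of length 5.
#' @export
ceres_threshold_grid <- function() {
  seq(-1.5, -0.5, length.out = 5)
}

#' Multiclass Matthews correlation coefficient
#'
#' The multiclass MCC over K classes,
#' `(c*s - sum(p_k*t_k)) / sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))`,
#' where `c` is the number of correct predictions, `s` the sample count,
#' and `p_k`/`t_k` the per-class prediction/truth counts. Degenerate
#' denominators (a constant predictor or constant truth) return 0.
#'
#' @param predicted,actual equal-length class vectors (any atomic type).
#' @return score in \[-1, 1\].
#' @export
mcc <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  classes <- union(predicted, actual)
  s <- length(predicted)
  cc <- sum(predicted == actual)
  p_k <- vapply(classes, function(k) sum(predicted == k), numeric(1))
  t_k <- vapply(classes, function(k) sum(actual == k), numeric(1))
  den2 <- (s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2))
  if (den2 <= 0) return(0)
  (cc * s - sum(p_k * t_k)) / sqrt(den2)
}

#' Discretize fluxes into activity classes
#'
#' @param v numeric flux vector (named by reaction).
#' @param tol symmetric tolerance around zero below which a flux is null.
#' @return named character vector with levels `"forward_active"`,
#'   `"reverse_active"`, `"null"`.
#' @export
discretize_flux <- function(v, tol = 1e-6) {
  out <- ifelse(v > tol, "forward_active",
                ifelse(v < -tol, "reverse_active", "null"))
  names(out) <- names(v)
  out
}

#' Compare predicted and measured flux activity
#'
#' Three-class MCC over the reactions present in both calls. Direction
#' conventions between the measurement source and the model are
#' reconciled beforehand by the caller via `sign_map`.
#'
#' @param predicted,measured named activity-class vectors (see
#'   [discretize_flux()]).
#' @param sign_map optional named numeric of +1/-1 applied to
#'   `predicted` reaction directions before comparison (a -1 swaps
#'   forward and reverse).
#' @return MCC score.
#' @export
compare_flux_activity <- function(predicted, measured, sign_map = NULL) {
  common <- intersect(names(predicted), names(measured))
  if (!length(common)) {
    stop("no overlapping reactions between predicted and measured calls")
  }
  p <- predicted[common]
  if (!is.null(sign_map)) {
    flip <- names(sign_map)[sign_map < 0]
    flip <- intersect(flip, common)
    p[flip] <- ifelse(p[flip] == "forward_active", "reverse_active",
                      ifelse(p[flip] == "reverse_active", "forward_active",
                             p[flip]))
  }
  mcc(p, measured[common])
}

#' Reconstruction-parameter importance by one-hot regression
#'
#' Fits an ordinary least-squares model of a performance score (e.g.
#' essentiality MCC) on one-hot encoded reconstruction parameters. One
#' reference level per parameter (the alphabetically first) is absorbed
#' into the intercept; parameters with a single observed value are
#' excluded. A rank-deficient design after dropping raises an error
#' naming the collinear options.
#'
#' @param configs data frame of reconstruction parameters (one row per
#'   model), e.g. from [parameter_grid()].
#' @param scores numeric performance score per row of `configs`.
#' @return data frame with `parameter`, `option`, `coefficient`,
#'   `std_error`; the intercept appears as parameter `"(Intercept)"`.
#' @export
parameter_importance <- function(configs, scores) {
  stopifnot(nrow(configs) == length(scores))
  use <- vapply(configs, function(col) length(unique(col[!is.na(col)])) > 1,
                logical(1))
  if (!any(use)) stop("no parameter varies across configurations")
  df <- configs[use]
  # percentiles unused by a strategy are NA in the grid; they are a real
  # design level ("unused"), not missing data
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "unused"
    factor(col)
  })
  df$.score <- scores
  fit <- stats::lm(.score ~ ., data = df)
  cf <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank-deficient; collinear option(s): ",
         paste(bad, collapse = ", "))
  }
  terms <- rownames(cf)
  par_of <- vapply(terms, function(t) {
    if (t == "(Intercept)") return("(Intercept)")
    hit <- names(df)[startsWith(t, names(df)) & names(df) != ".score"]
    hit[which.max(nchar(hit))]
  }, "")
  opt_of <- mapply(function(t, p) {
    if (t == "(Intercept)") "" else substring(t, nchar(p) + 1L)
  }, terms, par_of)
  data.frame(parameter = unname(par_of), option = unname(opt_of),
             coefficient = unname(cf[, 1]), std_error = unname(cf[, 2]),
             stringsAsFactors = FALSE)
}
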