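# Downstream analysis of predicted flux distributions: sigmoid scaling,
# variance/ANOVA feature selection, PCA-loading summarization by pathway,
# and cell-line-grouped cross-validation splits.

#' Sigmoid flux scaling
#'
#' `s(x) = a * (1 / (1 + exp(x))) + 1` applied elementwise. With the
#' default `a = -2` this is algebraically `tanh(x/2)`: odd,
#' sign-preserving, strictly increasing and bounded in (-1, 1), which
#' compresses very large fluxes while keeping directionality intact for
#' interpretation.
#'
#' @param v numeric flux values (vector or matrix).
#' @param a range parameter; 0 is rejected (the map would be constant).
#' @return scaled values with the same shape as `v`.
#' @export
scale_fluxes <- function(v, a = -2) {
  if (a == 0) stop("a = 0 gives a constant map; choose a nonzero range")
  a * (1 / (1 + exp(v))) + 1
}

#' Variance + ANOVA flux feature selection
#'
#' Drops features (columns) whose variance falls below a floor, then
#' ranks the survivors by one-way ANOVA p-value of the class labels and
#' keeps the `n_top` most significant. Ties in p-value break by larger
#' F statistic, then by column order.
#'
#' @param X numeric matrix, samples (rows) x flux features (columns).
#' @param labels class label per row; at least two classes with two or
#'   more rows each.
#' @param n_top number of features to keep (200 in typical use); if
#'   fewer survive the variance filter, all survivors are returned with
#'   a warning.
#' @param var_floor minimum column variance.
#' @return the reduced matrix, with attribute `ranking` (a data frame of
#'   kept features with their F and p values).
#' @export
select_flux_features <- function(X, labels, n_top = 200, var_floor = 1e-8) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need at least two classes with two or more samples each")
  }
  vars <- apply(X, 2, stats::var)
  keep <- which(vars >= var_floor)
  if (!length(keep)) stop("no feature passes the variance floor")
  stat <- vapply(keep, function(j) {
    ft <- stats::oneway.test(X[, j] ~ labels, var.equal = TRUE)
    c(ft$statistic, ft$p.value)
  }, numeric(2))
  ord <- order(stat[2, ], -stat[1, ], seq_along(keep))
  if (length(keep) < n_top) {
    warning("only ", length(keep), " features survive the variance filter ",
            "(requested ", n_top, "); returning all survivors")
  }
  sel <- keep[ord][seq_len(min(n_top, length(keep)))]
  out <- X[, sel, drop = FALSE]
  attr(out, "ranking") <- data.frame(
    feature = colnames(X)[sel] %||% as.character(sel),
    f_statistic = stat[1, ord][seq_len(length(sel))],
    p_value = stat[2, ord][seq_len(length(sel))],
    stringsAsFactors = FALSE
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize PCA loadings by metabolic pathway
#'
#' For each component, every flux weight is expressed as the absolute
#' ratio to the component's largest absolute weight, and ratios are
#' averaged within each pathway — a per-pathway relevance score in
#' \[0, 1\] that is invariant to rescaling a component's loading vector.
#' Fluxes without a pathway assignment fall into `"unassigned"`.
#'
#' @param loadings numeric matrix, fluxes (rows, named) x components.
#' @param pathway_map named character vector: reaction -> pathway.
#' @return matrix, pathways x components.
#' @export
pathway_loading_summary <- function(loadings, pathway_map) {
  loadings <- as.matrix(loadings)
  if (is.null(rownames(loadings))) stop("loadings must have reaction rownames")
  pw <- pathway_map[rownames(loadings)]
  pw[is.na(pw)] <- "unassigned"
  paths <- sort(unique(pw))
  out <- matrix(NA_real_, length(paths), ncol(loadings),
                dimnames = list(paths, colnames(loadings)))
  for (cmp in seq_len(ncol(loadings))) {
    w <- abs(loadings[, cmp])
    wmax <- max(w)
    if (wmax == 0) {
      stop("component ", cmp, " has an all-zero loading vector")
    }
    ratio <- w / wmax
    for (p in paths) out[p, cmp] <- mean(ratio[pw == p])
  }
  out
}

#' Cell-line-grouped k-fold cross-validation splits
#'
#' Partitions the distinct groups (cell lines) into k folds so that all
#' rows of a group land in the same fold — no group ever appears in both
#' the training and the test side of a split. Group order is shuffled
#' with the session RNG when `shuffle = TRUE`, so splits are
#' reproducible under `set.seed()`.
#'
#' @param groups group label per row.
#' @param k number of folds; must not exceed the number of distinct
#'   groups.
#' @param shuffle randomize group-to-fold assignment.
#' @return list of `k` lists with integer `train` and `test` row indices.
#' @export
grouped_kfold <- function(groups, k, shuffle = TRUE) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (k > length(gs)) {
    stop("k = ", k, " exceeds the number of distinct groups (", length(gs), ")")
  }
  if (shuffle) gs <- sample(gs)
  fold_of <- rep(seq_len(k), length.out = length(gs))
  lapply(seq_len(k), function(f) {
    test_groups <- gs[fold_of == f]
    test <- which(groups %in% test_groups)
    list(train = setdiff(seq_along(groups), test), test = test)
  })
}
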