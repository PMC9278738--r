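# Transcript activity scoring: turn a transcript-by-sample TPM matrix into
# per-transcript activity scores (TAS) relative to local and global
# expression thresholds. Three strategies are supported: a single global
# threshold, a local threshold for low expression (localT1), and a
# two-global-threshold scheme with an uncertainty band resolved locally
# (localT2).

#' Per-transcript local thresholds
#'
#' The local threshold of a transcript is a quantile of its expression
#' across samples. Quantiles use linear interpolation between order
#' statistics (R's default type 7), so thresholds are bit-reproducible.
#'
#' @param expr numeric matrix, transcripts (rows, named) x samples
#'   (columns), TPM; negative entries are rejected.
#' @param p percentile in (0, 100); the reconstruction grid uses
#'   10/25/50/75/90.
#' @return named numeric vector of thresholds (one per transcript).
#' @export
local_thresholds <- function(expr, p) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (ncol(expr) < 2) {
    stop("local thresholding needs at least 2 samples ",
         "(a quantile across samples is undefined otherwise)")
  }
  stopifnot(p > 0, p < 100)
  apply(expr, 1, stats::quantile, probs = p / 100, names = FALSE, type = 7)
}

#' Global threshold from a local threshold set
#'
#' A single representative expression value for the whole dataset: the
#' arithmetic mean of the per-transcript local thresholds at the chosen
#' percentile.
#'
#' @param local numeric vector of per-transcript thresholds.
#' @return scalar threshold.
#' @export
global_threshold <- function(local) {
  stopifnot(length(local) > 0)
  mean(local)
}

#' Assemble the thresholds a strategy needs
#'
#' @param expr transcript-by-sample TPM matrix.
#' @param strategy `"global"`, `"localT1"`, or `"localT2"`.
#' @param p_gmax percentile for the upper global threshold `g_max`.
#' @param p_gmin percentile for the lower global threshold `g_min`
#'   (localT2 only; must be below `p_gmax`).
#' @param p_local percentile for the per-transcript local thresholds
#'   (localT1/localT2).
#' @return object of class `threshold_set` with elements `strategy`,
#'   `g_max`, and where applicable `g_min` and `local`.
#' @export
threshold_set <- function(expr, strategy = c("global", "localT1", "localT2"),
                          p_gmax = 75, p_gmin = 25, p_local = 50) {
  strategy <- match.arg(strategy)
  out <- list(strategy = strategy,
              g_max = global_threshold(local_thresholds(expr, p_gmax)),
              p_gmax = p_gmax)
  if (strategy == "localT2") {
    if (!(p_gmin < p_gmax)) {
      stop("localT2 requires p_gmin < p_gmax (got ", p_gmin, " >= ", p_gmax, ")")
    }
    out$g_min <- global_threshold(local_thresholds(expr, p_gmin))
    out$p_gmin <- p_gmin
  }
  if (strategy %in% c("localT1", "localT2")) {
    out$local <- local_thresholds(expr, p_local)
    out$p_local <- p_local
  }
  structure(out, class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> strategy: ", x$strategy,
      "; g_max = ", format(x$g_max), sep = "")
  if (!is.null(x$g_min)) cat("; g_min = ", format(x$g_min), sep = "")
  if (!is.null(x$local)) cat("; |local| = ", length(x$local), sep = "")
  cat("\n")
  invisible(x)
}

#' Transcript activity scores for one sample
#'
#' Scores are log-ratios of expression to a reference threshold chosen by
#' the transcript's activity state:
#' \describe{
#'   \item{global}{`TAS = log(x / g_max)` for all transcripts.}
#'   \item{localT1}{`log(x / l(y))` below `g_max`; `log(x / g_max)`
#'     (non-negative) at or above it.}
#'   \item{localT2}{`1 + log(x / g_max)` at or above `g_max` (so the
#'     confidently-active range starts at 1); `log(x / g_min)`
#'     (non-positive) at or below `g_min`; otherwise the uncertainty band
#'     score `log(x / l(y))` clipped to `[-1, 1]`.}
#' }
#' Boundary values go to the outer, certain states: `x >= g_max` is
#' scored as active and `x <= g_min` as inactive. Zero expression yields
#' the configured floor on unbounded branches.
#'
#' @param x named numeric vector of expression values (one sample), TPM.
#' @param thresholds a [threshold_set()] whose `local` names cover `x`
#'   for the local strategies.
#' @param base logarithm base (2 by convention for fold changes).
#' @param floor finite score substituted for `log(0)` on unbounded
#'   branches; its negation caps ratios against a zero threshold.
#' @return named numeric vector of TAS with attribute `strategy`.
#' @export
compute_tas <- function(x, thresholds, base = 2, floor = -10) {
  if (!inherits(thresholds, "threshold_set")) {
    stop("'thresholds' must be a threshold_set")
  }
  if (any(x < 0)) stop("expression values must be non-negative")
  strategy <- thresholds$strategy
  lg <- function(num, den) {
    r <- log(num / den, base = base)
    r[num == 0 & den > 0] <- floor
    r[num > 0 & den == 0] <- -floor
    r[num == 0 & den == 0] <- floor
    r
  }
  g_max <- thresholds$g_max
  if (strategy == "global") {
    tas <- lg(x, g_max)
  } else {
    loc <- thresholds$local[names(x)]
    if (anyNA(loc)) {
      stop("local thresholds missing for transcript(s): ",
           paste(utils::head(names(x)[is.na(loc)], 5), collapse = ", "))
    }
    if (strategy == "localT1") {
      tas <- ifelse(x >= g_max, lg(x, g_max), lg(x, loc))
    } else {
      g_min <- thresholds$g_min
      mid <- pmin(pmax(lg(x, loc), -1), 1)
      tas <- ifelse(x >= g_max, 1 + lg(x, g_max),
                    ifelse(x <= g_min, lg(x, g_min), mid))
    }
  }
  names(tas) <- names(x)
  attr(tas, "strategy") <- strategy
  tas
}

#' TAS matrix for all samples of an expression matrix
#'
#' @param expr transcript-by-sample TPM matrix.
#' @param thresholds a [threshold_set()] computed from (typically) the
#'   same matrix.
#' @inheritParams compute_tas
#' @return matrix of scores with the same dimnames as `expr`.
#' @export
compute_tas_matrix <- function(expr, thresholds, base = 2, floor = -10) {
  expr <- as.matrix(expr)
  out <- vapply(seq_len(ncol(expr)), function(j) {
    as.numeric(compute_tas(stats::setNames(expr[, j], rownames(expr)),
                           thresholds, base = base, floor = floor))
  }, numeric(nrow(expr)))
  dimnames(out) <- dimnames(expr)
  out
}
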