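# End-to-end orchestration: preprocess (consistency + scoring), grid
# reconstruction with optional gap filling, and validation. Every stage
# writes TSV outputs plus a JSON manifest carrying the seed and
# parameters needed to reproduce the run exactly.

write_manifest <- function(out_dir, stage, info) {
  info$stage <- stage
  info$package_version <- tryCatch(
    as.character(utils::packageVersion("csgem")), error = function(e) "dev")
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(info, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

write_tsv_matrix <- function(x, path) {
  utils::write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Preprocess a template model and expression matrix
#'
#' Removes boundary metabolites and blocked reactions from the template,
#' computes thresholds, TAS and RAS under one configuration, and writes
#' everything (consistent model SBML, TAS/RAS TSVs, manifest) to the
#' output directory.
#'
#' @param model template [metabolic_model()] or SBML path.
#' @param expr transcript-by-sample TPM matrix or TSV path (transcripts
#'   in rows).
#' @param out_dir output directory (created if needed).
#' @param strategy,p_gmax,p_gmin,p_local thresholding configuration
#'   (see [threshold_set()]).
#' @param or_fn,and_fn GPR integration functions (see [compute_ras()]).
#' @param seed integer recorded in the manifest (preprocessing itself is
#'   deterministic).
#' @return list with `model` (consistent model), `thresholds`, `tas`
#'   (matrix), `ras` (matrix reactions x samples), `missing_genes`.
#' @export
run_preprocess <- function(model, expr, out_dir,
                           strategy = "localT2", p_gmax = 75, p_gmin = 25,
                           p_local = 50, or_fn = "max", and_fn = "min",
                           seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(model)) model <- read_sbml(model)
  if (is.character(expr)) expr <- read_tsv_matrix(expr)

  model <- remove_boundary_metabolites(model)
  blocked <- find_blocked_reactions(model)
  consistent <- set_bounds(model, blocked, lb = 0, ub = 0)

  thresholds <- threshold_set(expr, strategy, p_gmax = p_gmax,
                              p_gmin = p_gmin, p_local = p_local)
  tas <- compute_tas_matrix(expr, thresholds)

  genes <- model_genes(consistent)
  missing_genes <- setdiff(genes, rownames(expr))
  ras <- vapply(seq_len(ncol(tas)), function(j) {
    compute_ras(consistent, tas[, j], or_fn = or_fn, and_fn = and_fn)$ras
  }, numeric(length(consistent$reaction_ids)))
  dimnames(ras) <- list(consistent$reaction_ids, colnames(tas))

  write_sbml(consistent, file.path(out_dir, "consistent_model.xml"))
  write_tsv_matrix(tas, file.path(out_dir, "tas.tsv"))
  write_tsv_matrix(ras, file.path(out_dir, "ras.tsv"))
  write_manifest(out_dir, "preprocess", list(
    seed = seed, strategy = strategy, p_gmax = p_gmax,
    p_gmin = if (strategy == "localT2") p_gmin else NA,
    p_local = if (strategy != "global") p_local else NA,
    or_fn = or_fn, and_fn = and_fn,
    n_blocked = length(blocked), blocked = blocked,
    n_missing_genes = length(missing_genes), missing_genes = missing_genes
  ))
  list(model = consistent, thresholds = thresholds, tas = tas, ras = ras,
       blocked = blocked, missing_genes = missing_genes)
}

#' Reconstruct context-specific models over a configuration grid
#'
#' Runs FASTCORE or tINIT for each configuration row, optionally
#' gap-fills models that fail the growth check, and writes one presence
#' TSV plus a check report per configuration. Failures of individual
#' configurations are caught and logged, not propagated.
#'
#' @param pre result of [run_preprocess()] (the RAS of its sample
#'   `sample` is used), or an equivalent list.
#' @param configs data frame of configurations ([parameter_grid()] rows:
#'   `algorithm`, `or_fn`, ... — thresholding columns are informational
#'   here since `pre` fixed the scores).
#' @param sample column of the RAS matrix to reconstruct from.
#' @param out_dir output directory.
#' @param gapfill gap-fill models that cannot grow (intracellular
#'   scenario, biomass objective).
#' @param eps extraction flux threshold.
#' @param seed integer recorded in the manifest.
#' @return list of per-config results (`presence`, `check`, `gapfilled`,
#'   `error`).
#' @export
run_reconstruct <- function(pre, configs, sample = 1L, out_dir,
                            gapfill = FALSE, eps = 1e-4, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- pre$model
  ras_vec <- stats::setNames(pre$ras[, sample], rownames(pre$ras))
  has_gpr <- nzchar(trimws(model$gpr_rules))
  results <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    tag <- sprintf("cfg%03d_%s", i, cfg$algorithm)
    res <- tryCatch({
      r <- if (cfg$algorithm == "FASTCORE") {
        core <- model$reaction_ids[has_gpr & ras_vec > 0]
        fastcore(model, core, eps = eps)
      } else {
        tinit(model, ras_vec, protected = model$objective_id, eps = eps)
      }
      ctx <- apply_presence(model, r)
      chk <- check_model(ctx)
      gf <- NULL
      if (gapfill && !chk$grows) {
        sol <- efm_gapfill(build_gapfill_problem(model, r, model$objective_id))
        if (sol$status == "optimal") {
          r[sol$selected] <- 1L
          # the intracellular scenario treats exchange availability as a
          # medium question, not an enzyme question: exchanges stay open
          # in the gap-filled model, matching the problem it solved
          r[exchange_reactions(model)] <- 1L
          ctx <- apply_presence(model, r)
          chk <- check_model(ctx)
          gf <- sol$selected
        }
      }
      utils::write.table(
        data.frame(reaction_id = names(r), present = as.integer(r)),
        file.path(out_dir, paste0(tag, "_presence.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      list(presence = r, check = chk, gapfilled = gf, error = NULL)
    }, error = function(e) list(presence = NULL, check = NULL,
                                gapfilled = NULL,
                                error = conditionMessage(e)))
    results[[i]] <- res
  }
  write_manifest(out_dir, "reconstruct", list(
    seed = seed, n_configs = nrow(configs), gapfill = gapfill, eps = eps,
    failures = sum(vapply(results, function(r) !is.null(r$error), logical(1)))
  ))
  results
}

#' Validate reconstructed models
#'
#' Scores each successfully reconstructed model by in-silico gene
#' essentiality against CERES-style experimental scores across the
#' threshold grid, and (when measured flux calls are supplied) by
#' flux-activity MCC from a pFBA prediction. When two or more models
#' were scored, a parameter-importance regression over the
#' configurations is attempted.
#'
#' @param pre result of [run_preprocess()].
#' @param recon result of [run_reconstruct()].
#' @param configs the configuration grid used for `recon`.
#' @param ceres_scores named numeric experimental gene scores (optional).
#' @param measured_flux named activity-class vector (optional; see
#'   [discretize_flux()]).
#' @param out_dir output directory.
#' @param ceres_thresholds essentiality cutoffs,
#'   default [ceres_threshold_grid()].
#' @param seed integer recorded in the manifest.
#' @return list with `essentiality_mcc` (long data frame),
#'   `flux_mcc`, `importance` (or `NULL` where inputs were absent).
#' @export
run_validate <- function(pre, recon, configs, ceres_scores = NULL,
                         measured_flux = NULL, out_dir,
                         ceres_thresholds = ceres_threshold_grid(),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ceres_scores) && is.null(measured_flux)) {
    message("no validation data supplied; nothing to do")
    return(invisible(list(essentiality_mcc = NULL, flux_mcc = NULL,
                          importance = NULL)))
  }
  model <- pre$model
  ess_rows <- list()
  flux_rows <- list()
  for (i in seq_along(recon)) {
    r <- recon[[i]]
    if (!is.null(r$error) || !isTRUE(r$check$grows)) next
    ctx <- apply_presence(model, r$presence)
    if (!is.null(ceres_scores)) {
      screened <- essentiality_screen(ctx, names(ceres_scores))
      for (th in ceres_thresholds) {
        truth <- discretize_ceres(ceres_scores, th)
        pred <- stats::setNames(screened$essential, screened$gene)[names(truth)]
        ess_rows[[length(ess_rows) + 1L]] <- data.frame(
          config = i, ceres_threshold = th,
          mcc = mcc(ifelse(pred, "essential", "non-essential"),
                    ifelse(truth, "essential", "non-essential"))
        )
      }
    }
    if (!is.null(measured_flux)) {
      pf <- pfba(ctx)
      if (pf$status == "optimal") {
        pred_calls <- discretize_flux(pf$values)
        flux_rows[[length(flux_rows) + 1L]] <- data.frame(
          config = i,
          mcc = compare_flux_activity(pred_calls, measured_flux)
        )
      }
    }
  }
  ess <- if (length(ess_rows)) do.call(rbind, ess_rows) else NULL
  flx <- if (length(flux_rows)) do.call(rbind, flux_rows) else NULL
  imp <- NULL
  if (!is.null(ess) && length(unique(ess$config)) >= 2) {
    mid <- stats::aggregate(mcc ~ config, ess, mean)
    imp <- tryCatch(
      parameter_importance(configs[mid$config, , drop = FALSE], mid$mcc),
      error = function(e) NULL
    )
  }
  if (!is.null(ess)) {
    utils::write.table(ess, file.path(out_dir, "essentiality_mcc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(flx)) {
    utils::write.table(flx, file.path(out_dir, "flux_mcc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(imp)) {
    utils::write.table(imp, file.path(out_dir, "parameter_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "validate", list(
    seed = seed, n_models_scored = length(unique(c(
      if (!is.null(ess)) ess$config, if (!is.null(flx)) flx$config))),
    ceres_thresholds = ceres_thresholds
  ))
  list(essentiality_mcc = ess, flux_mcc = flx, importance = imp)
}
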