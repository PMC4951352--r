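#' Configuration for the end-to-end discovery pipeline
#'
#' Thresholds default to the values used throughout the package:
#' 10% FDR for differential expression, 20% FDR for the Fisher reversal
#' screen, p < 0.01 for the univariate Cox filter, 5% FDR for category
#' enrichment, and chance concordance probability 1/2.
#'
#' Input is either a pair of dataset file blocks (`datasets`, a list of
#' two lists with elements `expression` and `clinical`, each a TSV path;
#' the first dataset is the training set, the second doubles as the
#' consistency screen and the validation set) or a synthetic block
#' (`synthetic`, a [synthetic_config()]; two cohorts are generated with
#' seeds `seed` and `seed + 1`).
#'
#' @param datasets List of two `list(expression=, clinical=)` path blocks,
#'   or `NULL` when `synthetic` is given.
#' @param synthetic A [synthetic_config()] object, or `NULL`.
#' @param de_fdr,pair_fdr,cox_p,enrich_fdr Stage thresholds in (0, 1].
#' @param pe Chance concordance probability.
#' @param gmt Optional path to a GMT file for category enrichment.
#' @param seed Integer seed echoed to the run log and used for synthetic
#'   generation.
#' @return list of class `reosig_pipeline_config`.
#' @export
pipeline_config <- function(datasets = NULL, synthetic = NULL,
                            de_fdr = 0.1, pair_fdr = 0.2, cox_p = 0.01,
                            enrich_fdr = 0.05, pe = 0.5, gmt = NULL,
                            seed = 1L) {
  thr <- c(de_fdr = de_fdr, pair_fdr = pair_fdr, cox_p = cox_p,
           enrich_fdr = enrich_fdr)
  if (any(thr <= 0 | thr > 1))
    stop("thresholds must lie in (0, 1]")
  if (is.null(datasets) == is.null(synthetic))
    stop("supply exactly one of datasets or synthetic")
  structure(list(datasets = datasets, synthetic = synthetic,
                 de_fdr = de_fdr, pair_fdr = pair_fdr, cox_p = cox_p,
                 enrich_fdr = enrich_fdr, pe = pe, gmt = gmt,
                 seed = as.integer(seed)),
            class = "reosig_pipeline_config")
}

#' @keywords internal
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full gene-pair signature discovery pipeline
#'
#' Executes, on two datasets, the discovery chain: cohort selection,
#' metastatic differential expression (stage III/IV vs stage I), the
#' Fisher reversal screen per dataset, the cross-dataset consistency
#' filter, the univariate Cox prognosis filter on the first dataset's
#' stage II no-chemotherapy cohort, greedy forward selection of the
#' signature, risk classification of the training and validation stage II
#' cohorts with survival evaluation (log-rank, hazard ratio, C-index),
#' risk-based differential expression with cross-dataset concordance and
#' overlap against the metastatic DE genes, optional category enrichment,
#' and a chemotherapy-stratified comparison within each predicted risk
#' group. Every threshold and the seed are echoed to a machine-readable
#' run log.
#'
#' If no pair passes the Cox p threshold, the single smallest-p oriented
#' pair is used as the signature and noted in the log (threshold
#' degeneracy is tolerated rather than fatal).
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Run directory to create and populate.
#' @return Invisibly, a list with the in-memory results (`signature`,
#'   `train_eval`, `valid_eval`, `concordance`, `risk_calls`, `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "reosig_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list(thresholds = list(de_fdr = config$de_fdr,
                                pair_fdr = config$pair_fdr,
                                cox_p = config$cox_p,
                                enrich_fdr = config$enrich_fdr,
                                pe = config$pe),
              seed = config$seed, notes = character(0))

  data_sets <- run_stage("load", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      log$synthetic_config <- unclass(cfg)
      list(generate_cohort(cfg, dataset = 1L),
           generate_cohort(cfg, dataset = 2L))
    } else {
      lapply(config$datasets, function(d)
        list(expr = read_expression(d$expression),
             clinical = read_clinical(d$clinical)))
    }
  })

  screens <- run_stage("metastatic_screen", lapply(data_sets, function(d) {
    met <- select_cohort(d$clinical, c("III", "IV"))
    nonmet <- select_cohort(d$clinical, "I")
    de <- de_genes(d$expr, met, nonmet, fdr_threshold = config$de_fdr)
    rp <- reversed_pairs(d$expr, met, nonmet, de$gene_id,
                         fdr_threshold = config$pair_fdr)
    list(met = met, nonmet = nonmet, de = de, pairs = rp)
  }))
  log$n_metastatic_de <- vapply(screens, function(s) nrow(s$de), integer(1))
  log$n_reversed_pairs <- vapply(screens, function(s) nrow(s$pairs),
                                 integer(1))

  ov <- run_stage("consistent_overlap",
                  consistent_overlap(screens[[1]]$pairs, screens[[2]]$pairs))
  log$overlap <- list(k = ov$k, s = ov$s, score = ov$score)

  train_ids <- run_stage("train_cohort",
                         select_cohort(data_sets[[1]]$clinical, "II",
                                       ctx = FALSE))
  train_clin <- data_sets[[1]]$clinical[
    match(train_ids, data_sets[[1]]$clinical$sample_id), , drop = FALSE]

  pp <- run_stage("prognostic_pairs", suppressWarnings(
    prognostic_pairs(data_sets[[1]]$expr, train_clin, ov$survivors,
                     p_threshold = config$cox_p)))
  if (nrow(pp) == 0L) {
    log$notes <- c(log$notes,
                   "no pair passed the Cox threshold; using best pair")
    pp <- run_stage("prognostic_pairs_fallback", suppressWarnings(
      prognostic_pairs(data_sets[[1]]$expr, train_clin, ov$survivors,
                       p_threshold = 1)))
    if (nrow(pp) == 0L)
      stop("pipeline stage 'prognostic_pairs' failed: no usable pair")
    pp <- pp[1L, , drop = FALSE]
  }
  log$n_prognostic_pairs <- nrow(pp)

  sig <- run_stage("forward_select",
                   forward_select(pp, data_sets[[1]]$expr, train_clin))
  write_signature(sig, file.path(out_dir, "signature.json"))

  evaluate_cohort <- function(d, ids) {
    clin <- d$clinical[match(ids, d$clinical$sample_id), , drop = FALSE]
    calls <- classify_gps(d$expr, sig, ids)
    eval <- tryCatch(
      compare_survival(clin$rfs_time, clin$rfs_event, calls$label),
      error = function(e) list(error = conditionMessage(e)))
    list(calls = calls, clin = clin, eval = eval)
  }
  train <- run_stage("evaluate_train",
                     evaluate_cohort(data_sets[[1]], train_ids))
  valid_ids <- run_stage("validation_cohort",
                         select_cohort(data_sets[[2]]$clinical, "II",
                                       ctx = FALSE))
  valid <- run_stage("evaluate_validation",
                     evaluate_cohort(data_sets[[2]], valid_ids))
  utils::write.table(train$calls, file.path(out_dir, "risk_calls_train.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(valid$calls,
                     file.path(out_dir, "risk_calls_validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # risk-DE genes per dataset and their concordance with the metastatic
  # DE genes (the micro-metastasis check)
  risk_de <- run_stage("risk_de", lapply(seq_along(data_sets), function(i) {
    d <- data_sets[[i]]
    cohort <- if (i == 1L) train else valid
    hi <- cohort$calls$sample_id[cohort$calls$label == "high"]
    lo <- cohort$calls$sample_id[cohort$calls$label == "low"]
    if (length(hi) < 2L || length(lo) < 2L) return(NULL)
    de_genes(d$expr, hi, lo, fdr_threshold = config$de_fdr)
  }))
  concord <- run_stage("concordance", {
    res <- list()
    both <- !vapply(risk_de, is.null, logical(1))
    if (all(both)) {
      dir_a <- stats::setNames(risk_de[[1]]$direction, risk_de[[1]]$gene_id)
      dir_b <- stats::setNames(risk_de[[2]]$direction, risk_de[[2]]$gene_id)
      res$risk_de_between_datasets <-
        concordance_score(dir_a, dir_b, pe = config$pe)
    }
    for (i in which(both)) {
      met_dir <- stats::setNames(screens[[i]]$de$direction,
                                 screens[[i]]$de$gene_id)
      risk_dir <- stats::setNames(risk_de[[i]]$direction,
                                  risk_de[[i]]$gene_id)
      res[[paste0("risk_vs_metastatic_", i)]] <- list(
        overlap = overlap_test(risk_de[[i]]$gene_id,
                               screens[[i]]$de$gene_id,
                               nrow(data_sets[[i]]$expr)),
        concordance = concordance_score(risk_dir, met_dir, pe = config$pe))
    }
    res
  })

  enrichment <- NULL
  if (!is.null(config$gmt) && any(!vapply(risk_de, is.null, logical(1)))) {
    enrichment <- run_stage("enrichment", {
      de_tabs <- risk_de[!vapply(risk_de, is.null, logical(1))]
      genes <- if (length(de_tabs) >= 2L)
        consensus_de(de_tabs)$gene_id else de_tabs[[1]]$gene_id
      enrich_categories(genes, read_gmt(config$gmt),
                        rownames(data_sets[[1]]$expr),
                        fdr_threshold = config$enrich_fdr)
    })
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # chemotherapy benefit, stratified by predicted risk: pool stage II
  # samples (with and without CTX) across datasets and compare CTX vs
  # no-CTX within each predicted risk group
  ctx_strata <- run_stage("ctx_strata", {
    pooled <- do.call(rbind, lapply(seq_along(data_sets), function(i) {
      d <- data_sets[[i]]
      ids <- select_cohort(d$clinical, "II", ctx = "any")
      if (length(ids) == 0L) return(NULL)
      clin <- d$clinical[match(ids, d$clinical$sample_id), , drop = FALSE]
      calls <- classify_gps(d$expr, sig, ids)
      data.frame(dataset = i, sample_id = ids, ctx = clin$ctx,
                 rfs_time = clin$rfs_time, rfs_event = clin$rfs_event,
                 label = calls$label, stringsAsFactors = FALSE)
    }))
    out <- list()
    for (lab in c("low", "high")) {
      sub <- pooled[pooled$label == lab, , drop = FALSE]
      out[[lab]] <- tryCatch({
        lr <- logrank_test(sub$rfs_time, sub$rfs_event, sub$ctx)
        cf <- cox_fit(sub$rfs_time, sub$rfs_event,
                      data.frame(ctx = as.integer(sub$ctx)))
        list(n_ctx = sum(sub$ctx), n_noctx = sum(!sub$ctx),
             logrank_chi2 = lr$chi2, logrank_p = lr$p,
             hr_ctx = cf$coefficients$hr[1L],
             c_index = c_index(as.integer(sub$ctx),
                               sub$rfs_time, sub$rfs_event))
      }, error = function(e) list(error = conditionMessage(e)))
    }
    out
  })

  report <- list(signature = list(pairs = sig$pairs,
                                  vote_threshold = sig$vote_threshold,
                                  logrank_p = attr(sig, "logrank_p")),
                 train = train$eval, validation = valid$eval,
                 concordance = concord, ctx_strata = ctx_strata)
  jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log$package_version <- as.character(utils::packageVersion("reosig"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(signature = sig, train_eval = train$eval,
                 valid_eval = valid$eval, concordance = concord,
                 risk_calls = list(train = train$calls,
                                   validation = valid$calls),
                 ctx_strata = ctx_strata, log = log))
}
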