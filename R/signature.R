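#' Construct a gene-pair signature
#'
#' A signature is an ordered list of oriented gene pairs plus a strict
#' majority vote threshold. Each pair carries a `high_risk_reo` code:
#' `"lt"` means the within-sample ordering Ea < Eb votes for high risk,
#' `"gt"` means Ea > Eb does. The default threshold is the strict majority
#' `floor(n/2) + 1` (2 of 3 for a three-pair signature).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`,
#'   `high_risk_reo` (`"lt"`/`"gt"`), and optionally `cox_p`, `cox_hr`.
#' @param vote_threshold Override the strict-majority default.
#' @return Object of class `reo_signature`.
#' @export
reo_signature <- function(pairs, vote_threshold = NULL) {
  req <- c("gene_a", "gene_b", "high_risk_reo")
  if (!is.data.frame(pairs) || !all(req %in% colnames(pairs)))
    stop("pairs must be a data.frame with gene_a, gene_b, high_risk_reo")
  if (nrow(pairs) == 0L) stop("signature must contain >= 1 pair")
  if (any(pairs$gene_a == pairs$gene_b))
    stop("a pair cannot repeat one gene")
  if (!all(pairs$high_risk_reo %in% c("lt", "gt")))
    stop("high_risk_reo must be \"lt\" or \"gt\"")
  if (is.null(vote_threshold))
    vote_threshold <- nrow(pairs) %/% 2L + 1L
  vote_threshold <- as.integer(vote_threshold)
  if (vote_threshold < 1L || vote_threshold > nrow(pairs))
    stop("vote_threshold out of range")
  structure(list(pairs = as.data.frame(pairs, stringsAsFactors = FALSE),
                 vote_threshold = vote_threshold),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("Gene-pair signature: %d pair(s), high risk at >= %d vote(s)\n",
              nrow(x$pairs), x$vote_threshold))
  show <- x$pairs
  show$rule <- ifelse(show$high_risk_reo == "lt",
                      paste(show$gene_a, "<", show$gene_b),
                      paste(show$gene_a, ">", show$gene_b))
  print(show[, c("rule", intersect(c("cox_p", "cox_hr"), colnames(show))),
             drop = FALSE], digits = 4)
  invisible(x)
}

#' Write / read a signature as JSON
#'
#' @param signature A [reo_signature()] object.
#' @param path JSON file path.
#' @return `path` (write) or the signature (read).
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "reo_signature"))
  jsonlite::write_json(list(pairs = signature$pairs,
                            vote_threshold = signature$vote_threshold),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  reo_signature(as.data.frame(obj$pairs, stringsAsFactors = FALSE),
                vote_threshold = obj$vote_threshold)
}

#' The published three-pair relapse-risk signature (3-GPS)
#'
#' The three oriented gene pairs ORC1-OLR1, MTNR1A-VGLL1 and RFX5-MMP14,
#' each voting high risk when the first gene's expression is below the
#' second gene's within a sample, with a 2-of-3 majority threshold. Shipped
#' for the classify-only workflow on gene-level matrices that contain these
#' six genes.
#'
#' @return A [reo_signature()] object.
#' @export
gps3_signature <- function() {
  read_signature(system.file("extdata", "gps3_signature.json",
                             package = "reosig", mustWork = TRUE))
}

# Univariate Cox of the REO partition of one pair, via the bare
# survival::coxph.fit engine (the formula interface is too slow for the
# tens of thousands of fits the pair screen produces). Score-test fallback
# under monotone likelihood (e.g. an immortal group), where the Wald test
# degenerates. `y` is a pre-sorted Surv object and `grp_gt` the REO
# indicator in the same order. Returns NULL for a degenerate partition.
#' @keywords internal
pair_cox <- function(grp_gt, y, control) {
  fit <- suppressWarnings(survival::coxph.fit(
    matrix(as.double(grp_gt), ncol = 1L), y, strata = NULL, offset = NULL,
    init = NULL, control = control, weights = NULL, method = "efron",
    rownames = NULL))
  beta <- unname(fit$coefficients[1L])
  if (!is.finite(beta)) return(NULL)
  monotone <- abs(beta) > 15 || fit$iter >= control$iter.max
  p <- if (monotone) {
    stats::pchisq(fit$score, df = 1L, lower.tail = FALSE)
  } else {
    stats::pchisq(beta^2 / fit$var[1L, 1L], df = 1L, lower.tail = FALSE)
  }
  # orient: high_risk_reo is the ordering of the worse-survival group
  high_reo <- if (beta > 0) "gt" else "lt"
  list(p = p, hr = exp(abs(beta)), high_risk_reo = high_reo,
       monotone = monotone)
}

#' Filter gene pairs to prognosis-associated oriented pairs
#'
#' For each candidate pair, the cohort is partitioned by the pair's
#' within-sample ordering and a univariate Cox proportional-hazards model
#' is fitted with the binary partition as covariate. Pairs whose Wald p
#' falls below `p_threshold` are retained and oriented so that
#' `high_risk_reo` is the ordering of the worse-survival group; `cox_hr`
#' is the hazard ratio of that group versus the other. Under monotone
#' likelihood (perfect separation of an event-free group) the score-test p
#' is used and a warning is issued.
#'
#' Pairs whose partition is degenerate or nearly so are skipped with a
#' message: both orderings must occur in at least a fraction
#' `min_group_frac` of the cohort. A hazard ratio estimated from a
#' near-empty stratum is meaningless, and the log-rank statistic used
#' downstream is badly anti-conservative for such partitions (a single
#' early-relapsing sample against the rest of the cohort can produce an
#' astronomically small p), so these pairs are treated like the
#' empty-partition case rather than passed to the selection stage.
#'
#' @param expr Expression matrix.
#' @param clinical Clinical table; its samples define the cohort
#'   (typically the stage II, no-chemotherapy subset).
#' @param pairs data.frame with columns `gene_a`, `gene_b` (e.g. the
#'   survivors of [consistent_overlap()]).
#' @param p_threshold Wald p cutoff, default 0.01.
#' @param min_group_frac Minimum fraction of the cohort required on each
#'   side of the REO partition (default 0.1, the conventional 10%-90%
#'   restriction used when screening dichotomized prognostic markers).
#' @return data.frame of oriented pairs: `gene_a`, `gene_b`,
#'   `high_risk_reo`, `cox_p`, `cox_hr`, ordered by p.
#' @export
prognostic_pairs <- function(expr, clinical, pairs, p_threshold = 0.01,
                             min_group_frac = 0.1) {
  validate_expression(expr)
  clinical <- validate_clinical(clinical)
  samples <- clinical$sample_id
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_s) > 0L)
    stop("clinical samples absent from expression matrix: ",
         paste(utils::head(missing_s, 5L), collapse = ", "))
  if (any(is.na(clinical$rfs_time)))
    stop("cohort contains missing RFS annotations; filter with select_cohort")
  ord <- order(clinical$rfs_time)
  samples <- samples[ord]
  y <- survival::Surv(clinical$rfs_time[ord], clinical$rfs_event[ord])
  control <- survival::coxph.control()
  n <- length(samples)
  min_group <- max(1L, ceiling(min_group_frac * n))
  n_skip <- 0L
  n_monotone <- 0L
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- c(pairs$gene_a[i], pairs$gene_b[i])
    grp_gt <- expr[pr[1L], samples] > expr[pr[2L], samples]
    n_gt <- sum(grp_gt)
    if (n_gt < min_group || n - n_gt < min_group) {
      n_skip <- n_skip + 1L; next
    }
    fit <- pair_cox(grp_gt, y, control)
    if (is.null(fit)) { n_skip <- n_skip + 1L; next }
    if (fit$monotone) n_monotone <- n_monotone + 1L
    res[[i]] <- data.frame(gene_a = pr[1L], gene_b = pr[2L],
                           high_risk_reo = fit$high_risk_reo,
                           cox_p = fit$p, cox_hr = fit$hr,
                           stringsAsFactors = FALSE)
  }
  if (n_skip > 0L)
    message(n_skip,
            " pair(s) skipped: degenerate or near-degenerate REO partition")
  if (n_monotone > 0L)
    warning(n_monotone,
            " pair(s) showed monotone likelihood; score-test p used")
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      high_risk_reo = character(), cox_p = numeric(),
                      cox_hr = numeric(), stringsAsFactors = FALSE))
  out <- out[out$cox_p < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$cox_p), , drop = FALSE]
}

#' Classify samples by majority vote of oriented gene pairs
#'
#' For each sample, count the pairs whose within-sample ordering equals
#' their `high_risk_reo`; the sample is labelled high risk when the count
#' reaches the signature's vote threshold (at least 2 of 3 for the
#' published signature). The orderings are strict, so an exact tie between
#' a pair's two values never votes for high risk. The label of a sample
#' depends only on that sample's own values: classifying it alone, in any
#' cohort, or after any strictly increasing per-sample transform of the
#' data gives the same answer.
#'
#' @param expr Expression matrix containing every signature gene.
#' @param signature A [reo_signature()] object.
#' @param samples Sample identifiers to classify (default: all columns).
#' @return data.frame with columns `sample_id`, `votes_high`, `label`.
#' @export
classify_gps <- function(expr, signature, samples = colnames(expr)) {
  validate_expression(expr)
  stopifnot(inherits(signature, "reo_signature"))
  missing_g <- setdiff(unique(c(signature$pairs$gene_a,
                                signature$pairs$gene_b)), rownames(expr))
  if (length(missing_g) > 0L)
    stop("signature gene(s) absent from expression matrix: ",
         paste(missing_g, collapse = ", "))
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_s) > 0L)
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 5L),
                                         collapse = ", "))
  votes <- rep(0L, length(samples))
  for (i in seq_len(nrow(signature$pairs))) {
    va <- expr[signature$pairs$gene_a[i], samples]
    vb <- expr[signature$pairs$gene_b[i], samples]
    hit <- if (signature$pairs$high_risk_reo[i] == "gt") va > vb else va < vb
    votes <- votes + as.integer(hit)
  }
  data.frame(sample_id = samples,
             votes_high = votes,
             label = ifelse(votes >= signature$vote_threshold, "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# log-rank p of the majority-vote classification induced by a pair set;
# p = 1 when the classification is degenerate (single group).
#' @keywords internal
signature_logrank_p <- function(expr, pairs, samples, times, events) {
  sig <- reo_signature(pairs)
  calls <- classify_gps(expr, sig, samples)
  if (length(unique(calls$label)) < 2L) return(1)
  logrank_test(times, events, calls$label)$p
}

#' Greedy forward selection of a gene-pair signature
#'
#' Starting from the candidate pair whose single-pair classification gives
#' the smallest log-rank p on the training cohort (the seed), each
#' iteration evaluates every unused candidate added to the current set
#' under the strict-majority vote rule and accepts the best-improving
#' addition; selection stops when no addition strictly decreases the
#' log-rank p (or candidates are exhausted). Ties are broken by smaller p,
#' then larger |log HR| of the candidate's univariate Cox fit, then
#' lexicographic pair identifier, so runs are deterministic.
#'
#' @param candidates Oriented pairs from [prognostic_pairs()] (must carry
#'   `cox_hr` for tie-breaking; a missing column is treated as HR 1).
#' @param expr Expression matrix.
#' @param clinical Training cohort clinical table.
#' @param max_size Optional cap on signature size.
#' @return A [reo_signature()] object; attribute `logrank_p` records the
#'   selected set's log-rank p.
#' @export
forward_select <- function(candidates, expr, clinical, max_size = Inf) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no candidate pairs")
  clinical <- validate_clinical(clinical)
  samples <- clinical$sample_id
  times <- clinical$rfs_time
  events <- clinical$rfs_event
  if (!"cox_hr" %in% colnames(candidates)) candidates$cox_hr <- 1
  key <- canonical_pair_key(candidates$gene_a, candidates$gene_b)
  if (anyDuplicated(key)) stop("duplicate candidate pairs")

  single_p <- vapply(seq_len(nrow(candidates)), function(i)
    signature_logrank_p(expr, candidates[i, , drop = FALSE],
                        samples, times, events), numeric(1))
  if (all(single_p >= 1))
    stop("all candidate pairs give degenerate classifications")
  ord <- order(single_p, -abs(log(candidates$cox_hr)), key)
  seed <- ord[1L]
  chosen <- seed
  best_p <- single_p[seed]
  repeat {
    if (length(chosen) >= min(max_size, nrow(candidates))) break
    remaining <- setdiff(seq_len(nrow(candidates)), chosen)
    trial_p <- vapply(remaining, function(i)
      signature_logrank_p(expr, candidates[c(chosen, i), , drop = FALSE],
                          samples, times, events), numeric(1))
    ord2 <- order(trial_p, -abs(log(candidates$cox_hr[remaining])),
                  key[remaining])
    best <- ord2[1L]
    if (trial_p[best] < best_p) {
      chosen <- c(chosen, remaining[best])
      best_p <- trial_p[best]
    } else break
  }
  sig <- reo_signature(candidates[chosen, , drop = FALSE])
  attr(sig, "logrank_p") <- best_p
  sig
}

#' Percentile-threshold voting classifier (risk-score baseline)
#'
#' Reimplements the cohort-dependent classification rule used by
#' percentile-based gene signatures: a gene indicates poor prognosis for a
#' sample when its expression lies above the 80th (if high expression is
#' risky) or below the 20th (if low expression is risky) percentile of its
#' values across the samples analyzed together, and a sample is labelled
#' high risk when at least `vote_min` genes indicate poor prognosis.
#'
#' The percentiles are computed over the provided sample set only, so a
#' sample's label can change when it is re-analyzed within a different
#' cohort. This instability is the point of the operation: it serves as
#' the contrast to [classify_gps()], whose calls depend only on each
#' sample's own within-sample orderings.
#'
#' @param expr Expression matrix.
#' @param genes data.frame with columns `gene_id` and `risky_when`
#'   (`"high"` or `"low"`: which expression extreme indicates poor
#'   prognosis).
#' @param vote_min Minimum number of poor-prognosis flags for a high-risk
#'   call.
#' @param hi_pct,lo_pct Percentile cutoffs (defaults 80 and 20).
#' @param samples Sample identifiers analyzed together.
#' @return data.frame with columns `sample_id`, `votes_high`, `label`.
#' @export
percentile_vote_classify <- function(expr, genes, vote_min,
                                     hi_pct = 80, lo_pct = 20,
                                     samples = colnames(expr)) {
  validate_expression(expr)
  if (!all(c("gene_id", "risky_when") %in% colnames(genes)))
    stop("genes must have columns gene_id, risky_when")
  if (!all(genes$risky_when %in% c("high", "low")))
    stop("risky_when must be \"high\" or \"low\"")
  if (nrow(genes) < 1L) stop("need >= 1 gene")
  if (vote_min > nrow(genes))
    stop("vote_min exceeds the number of genes")
  missing_g <- setdiff(genes$gene_id, rownames(expr))
  if (length(missing_g) > 0L)
    stop("gene(s) absent from expression matrix: ",
         paste(missing_g, collapse = ", "))
  flags <- rep(0L, length(samples))
  for (i in seq_len(nrow(genes))) {
    v <- expr[genes$gene_id[i], samples]
    flagged <- if (genes$risky_when[i] == "high") {
      v > stats::quantile(v, hi_pct / 100)
    } else {
      v < stats::quantile(v, lo_pct / 100)
    }
    flags <- flags + as.integer(flagged)
  }
  data.frame(sample_id = samples,
             votes_high = flags,
             label = ifelse(flags >= vote_min, "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}
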