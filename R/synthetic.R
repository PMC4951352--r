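#' Configuration for the synthetic CRC-like cohort generator
#'
#' The generator emulates the statistical structure that the gene-pair
#' discovery pipeline assumes in a multi-stage colorectal-cancer cohort:
#' a log2 expression matrix with planted gene pairs whose within-sample
#' ordering differs between metastatic (stage III/IV) and non-metastatic
#' (stage I) samples, a latent relapse-risk label for stage II samples that
#' drives both the planted orderings and an exponential relapse-free
#' survival model with independent censoring, planted
#' differentially-expressed genes carrying a fixed log2 mean shift in
#' metastatic samples (and, mirroring the micro-metastasis hypothesis, in
#' latent high-risk stage II samples), and adjuvant-chemotherapy arms with
#' stratum-specific multiplicative hazard effects.
#'
#' Defaults describe a cohort of verification-friendly desk scale: 1000
#' genes with baseline means drawn uniformly over the log2 dynamic range
#' 2-14 of the profiled transcriptome, 30 planted pairs showing their
#' high-risk ordering with probability 0.9 in metastatic / latent-high
#' samples and 0.1 in stage I / latent-low samples, a quarter of stage II
#' patients latently high-risk (matching the reported 25-30% relapse rate
#' of surgically treated stage II disease), a true hazard ratio of 4 for
#' high vs low risk, and a chemotherapy effect that is harmful in the
#' low-risk stratum (hazard x 2.8) and beneficial in the high-risk
#' stratum (hazard x 0.55). The per-gene noise (0.12 log2 units) is
#' deliberately tight relative to the spacing of the planted pairs across
#' the dynamic range, so that different planted pairs' expression ranges
#' do not overlap and each pair's signal stays attached to that pair;
#' real arrays carry broader biological variation, a fidelity limit
#' documented in the methods vignette.
#'
#' @param n_genes Number of genes.
#' @param n_stage1,n_stage2_noctx,n_stage2_ctx,n_stage34 Cohort sizes.
#' @param n_planted_pairs Number of planted reversed gene pairs; pairs are
#'   planted on disjoint genes so ground-truth recovery is unambiguous.
#' @param n_de_genes Number of planted differentially-expressed genes
#'   (disjoint from planted pair genes).
#' @param f_high Probability a planted pair shows its high-risk ordering
#'   in a metastatic or latent-high-risk sample.
#' @param f_low Same probability in stage I or latent-low-risk samples.
#' @param frac_stage2_highrisk Latent high-risk fraction among stage II.
#' @param baseline_hazard Relapse hazard (events/month) for low-risk samples.
#' @param hr_true Hazard ratio of latent high vs low risk; must be > 0
#'   (set to 1 for null calibration runs).
#' @param censor_rate Hazard of the independent exponential censoring time.
#' @param ctx_hr_low,ctx_hr_high Multiplicative hazard effect of adjuvant
#'   chemotherapy within the low- and high-risk strata.
#' @param de_shift Log2 mean shift of planted DE genes in metastatic
#'   samples (and latent-high stage II samples when `couple_risk_de`).
#' @param couple_risk_de Apply `de_shift` also to latent high-risk stage II
#'   samples, coupling relapse risk to the metastatic transcriptional
#'   phenotype (the micro-metastasis hypothesis). Off by default: the
#'   baseline generator confines the mean shift to stage III/IV so that
#'   the planted pairs are the only strong prognostic structure in
#'   stage II and ground-truth recovery is unambiguous; enable it to
#'   study risk-DE/metastatic-DE concordance.
#' @param noise_sd Per-gene Gaussian noise standard deviation (log2 units).
#' @param mean_range Range of the uniform per-gene baseline means.
#' @param pair_gap Maximum baseline-mean separation (log2 units) between
#'   the two genes of a planted pair.
#' @param seed Integer seed; the entire cohort is reproducible from it.
#' @return A list of class `reosig_config`.
#' @export
synthetic_config <- function(n_genes = 1000L,
                             n_stage1 = 40L,
                             n_stage2_noctx = 200L,
                             n_stage2_ctx = 40L,
                             n_stage34 = 60L,
                             n_planted_pairs = 30L,
                             n_de_genes = 50L,
                             f_high = 0.9,
                             f_low = 0.1,
                             frac_stage2_highrisk = 0.25,
                             baseline_hazard = 0.01,
                             hr_true = 4,
                             censor_rate = 0.02,
                             ctx_hr_low = 2.8,
                             ctx_hr_high = 0.55,
                             de_shift = 1,
                             couple_risk_de = FALSE,
                             noise_sd = 0.12,
                             mean_range = c(2, 14),
                             pair_gap = 0.25,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_stage1 = as.integer(n_stage1),
              n_stage2_noctx = as.integer(n_stage2_noctx),
              n_stage2_ctx = as.integer(n_stage2_ctx),
              n_stage34 = as.integer(n_stage34),
              n_planted_pairs = as.integer(n_planted_pairs),
              n_de_genes = as.integer(n_de_genes),
              f_high = f_high, f_low = f_low,
              frac_stage2_highrisk = frac_stage2_highrisk,
              baseline_hazard = baseline_hazard,
              hr_true = hr_true,
              censor_rate = censor_rate,
              ctx_hr_low = ctx_hr_low,
              ctx_hr_high = ctx_hr_high,
              de_shift = de_shift,
              couple_risk_de = isTRUE(couple_risk_de),
              noise_sd = noise_sd,
              mean_range = mean_range,
              pair_gap = pair_gap,
              seed = as.integer(seed))
  class(cfg) <- "reosig_config"
  validate_config(cfg)
  cfg
}

# Choose disjoint gene pairs with baseline means within `gap` of each
# other, spread evenly across the dynamic range: collect every
# mean-adjacent eligible pair, then take n_pairs of them at evenly spaced
# positions of the mean-sorted candidate list (skipping gene conflicts).
# Spreading keeps different planted pairs' expression ranges apart, so
# each pair's prognostic signal stays attached to that pair rather than
# to orderings across pairs. Deterministic given mu; consumes no
# randomness.
#' @keywords internal
pick_pair_genes <- function(mu, n_pairs, gap, exclude = integer(0)) {
  ord <- setdiff(order(mu), exclude)
  gaps <- diff(mu[ord])
  cand <- which(gaps <= gap)            # candidate = (ord[i], ord[i+1])
  # drop candidates sharing a gene with the previous candidate
  keep <- logical(length(cand))
  last <- -1L
  for (j in seq_along(cand)) {
    if (cand[j] > last + 1L || last < 0L) { keep[j] <- TRUE; last <- cand[j] }
  }
  cand <- cand[keep]
  if (length(cand) < n_pairs)
    stop("could not place ", n_pairs,
         " planted pairs with baseline means within ", gap,
         " log2 units; increase n_genes or pair_gap")
  take <- unique(round(seq(1L, length(cand), length.out = n_pairs)))
  # unique() can only shrink when candidates are scarce; top up if needed
  extra <- setdiff(seq_along(cand), take)
  take <- sort(c(take, extra[seq_len(n_pairs - length(take))]))
  sel <- cand[take]
  list(a = ord[sel], b = ord[sel + 1L])
}

#' @keywords internal
validate_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_stage1, cfg$n_stage2_noctx,
              cfg$n_stage2_ctx, cfg$n_stage34,
              cfg$n_planted_pairs, cfg$n_de_genes)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (!(cfg$f_low >= 0 && cfg$f_low < cfg$f_high && cfg$f_high <= 1))
    stop("require 0 <= f_low < f_high <= 1")
  if (cfg$hr_true <= 0) stop("hr_true must be > 0")
  if (2L * cfg$n_planted_pairs + cfg$n_de_genes > cfg$n_genes)
    stop("n_genes too small for the requested planted pairs and DE genes")
  if (cfg$baseline_hazard <= 0 || cfg$censor_rate <= 0)
    stop("hazards must be > 0")
  invisible(cfg)
}

#' Generate a synthetic cohort with planted reversed gene pairs
#'
#' Draw order is fixed so that a given seed yields a reproducible cohort,
#' and so that the gene-level background is identical across configurations
#' that differ only in the number of planted pairs: sample labels and
#' latent risk, then per-gene means, then the background matrix, then the
#' DE-gene shift, then the per-sample orientation draws with value swaps,
#' then survival times.
#'
#' The gene-level "biology" (per-gene baseline means, pair placement, DE
#' gene identity) is seeded by `config$seed` alone, while the sampled
#' cohort (noise, latent risk, orientation draws, survival) is seeded by
#' `config$seed + dataset`. Cohorts generated from the same config with
#' different `dataset` indices therefore measure the same planted gene
#' pairs in independent patient samples, emulating independent datasets
#' profiling one disease population -- the situation the cross-dataset
#' consistency filter assumes.
#'
#' Planted DE genes are the last `n_de_genes` genes (a choice independent
#' of the pair placement, so cohorts generated with and without planted
#' pairs share an identical background). Planted pairs are placed on
#' disjoint genes whose baseline means lie within `pair_gap` log2 units of
#' each other, found by scanning the drawn means: a relative-ordering
#' biomarker pair is only informative when the two genes' expression
#' ranges overlap, and placing pairs on overlapping-range genes also keeps
#' each pair gene's marginal distribution nearly unchanged by the
#' orientation forcing, so the planted pairs -- not shadows of their
#' member genes -- carry the prognostic signal. For each planted pair the
#' high-risk ordering is "first gene below second gene" (Ea < Eb). Per
#' sample, a Bernoulli draw with probability `f_high` (metastatic or
#' latent-high) or `f_low` (stage I or latent-low) decides whether the
#' high-risk ordering is shown; if the realized values contradict the
#' drawn orientation, the two values are swapped within that sample,
#' which enforces the intended ordering while preserving the sample's
#' value multiset.
#'
#' Relapse-free survival is exponential with hazard
#' `baseline_hazard * hr_true^[latent high] * ctx_effect`, censored by an
#' independent exponential with rate `censor_rate`; stage I samples are
#' treated as latent low risk, stage III/IV as latent high risk.
#'
#' @param config A [synthetic_config()] object.
#' @param dataset Dataset index (1, 2, ...): cohorts with the same config
#'   and different indices share gene-level structure but have independent
#'   samples.
#' @return A list with elements `expr` (numeric matrix), `clinical`
#'   (data.frame) and `truth` (list with `planted_pairs`, `latent_risk`,
#'   `planted_de_genes`, `dataset`, and the echoed `config`).
#' @export
generate_cohort <- function(config = synthetic_config(), dataset = 1L) {
  validate_config(config)
  # gene-level structure: means, pair placement, DE-gene identity
  set.seed(config$seed)
  mu <- stats::runif(config$n_genes, config$mean_range[1], config$mean_range[2])
  de_idx <- seq.int(config$n_genes - config$n_de_genes + 1L,
                    length.out = config$n_de_genes)
  sel <- if (config$n_planted_pairs > 0L)
    pick_pair_genes(mu, config$n_planted_pairs, config$pair_gap,
                    exclude = de_idx) else NULL
  # sampled cohort
  set.seed(config$seed + as.integer(dataset))
  n_samp <- config$n_stage1 + config$n_stage2_noctx +
    config$n_stage2_ctx + config$n_stage34
  stage2 <- config$n_stage2_noctx + config$n_stage2_ctx
  n34_half <- config$n_stage34 %/% 2L
  stage <- c(rep("I", config$n_stage1),
             rep("II", stage2),
             rep("III", n34_half),
             rep("IV", config$n_stage34 - n34_half))
  ctx <- c(rep(FALSE, config$n_stage1),
           rep(FALSE, config$n_stage2_noctx),
           rep(TRUE, config$n_stage2_ctx),
           rep(FALSE, config$n_stage34))
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  # latent relapse-risk label; deterministic for stage I (low) and III/IV (high)
  latent <- ifelse(stage %in% c("III", "IV"), "high", "low")
  is2 <- stage == "II"
  latent[is2] <- ifelse(
    stats::rbinom(sum(is2), 1L, config$frac_stage2_highrisk) == 1L,
    "high", "low")
  names(latent) <- sample_ids

  expr <- matrix(stats::rnorm(config$n_genes * n_samp, mean = mu,
                              sd = config$noise_sd),
                 nrow = config$n_genes, ncol = n_samp,
                 dimnames = list(gene_ids, sample_ids))

  # planted DE genes: +de_shift in metastatic samples, and (micro-metastasis
  # coupling, if enabled) in latent high-risk stage II samples
  shifted_cols <- stage %in% c("III", "IV")
  if (config$couple_risk_de)
    shifted_cols <- shifted_cols | (is2 & latent == "high")
  if (config$n_de_genes > 0L && any(shifted_cols))
    expr[de_idx, shifted_cols] <- expr[de_idx, shifted_cols] + config$de_shift

  planted_pairs <- NULL
  if (config$n_planted_pairs > 0L) {
    a_idx <- pmin(sel$a, sel$b)   # canonical: gene_a = lower index
    b_idx <- pmax(sel$a, sel$b)
    p_high <- ifelse(latent == "high", config$f_high, config$f_low)
    for (k in seq_len(config$n_planted_pairs)) {
      want_high <- stats::rbinom(n_samp, 1L, p_high) == 1L  # Ea < Eb votes high
      va <- expr[a_idx[k], ]
      vb <- expr[b_idx[k], ]
      swap <- (va < vb) != want_high
      expr[a_idx[k], swap] <- vb[swap]
      expr[b_idx[k], swap] <- va[swap]
    }
    planted_pairs <- data.frame(gene_a = gene_ids[a_idx],
                                gene_b = gene_ids[b_idx],
                                high_risk_reo = "lt",
                                stringsAsFactors = FALSE)
  }

  hazard <- config$baseline_hazard *
    ifelse(latent == "high", config$hr_true, 1) *
    ifelse(ctx, ifelse(latent == "high", config$ctx_hr_high,
                       config$ctx_hr_low), 1)
  t_event <- stats::rexp(n_samp, rate = hazard)
  t_cens <- stats::rexp(n_samp, rate = config$censor_rate)
  rfs_time <- pmin(t_event, t_cens)
  rfs_event <- as.integer(t_event <= t_cens)

  age <- round(stats::rnorm(n_samp, mean = 68, sd = 10))
  sex <- sample(c("male", "female"), n_samp, replace = TRUE)
  msi <- sample(c("MSI", "MSS", "unknown"), n_samp, replace = TRUE,
                prob = c(0.15, 0.75, 0.10))
  localization <- sample(c("distal", "proximal", "unknown"), n_samp,
                         replace = TRUE, prob = c(0.55, 0.40, 0.05))

  clinical <- data.frame(sample_id = sample_ids,
                         stage = stage,
                         ctx = ctx,
                         rfs_time = rfs_time,
                         rfs_event = rfs_event,
                         age = age,
                         sex = sex,
                         msi = msi,
                         localization = localization,
                         stringsAsFactors = FALSE)

  truth <- list(planted_pairs = planted_pairs,
                latent_risk = latent,
                planted_de_genes = if (config$n_de_genes > 0L)
                  gene_ids[de_idx] else character(0),
                dataset = as.integer(dataset),
                config = unclass(config))
  list(expr = expr, clinical = clinical, truth = truth)
}

#' Write a synthetic cohort as plain-text fixture files
#'
#' Emits `expression.tsv` and `clinical.tsv` in the dialects read by
#' [read_expression()] / [read_clinical()], plus a `truth.json` sidecar
#' recording the planted pairs, the latent risk labels, the planted DE
#' genes and the full generator configuration (including the seed, so the
#' cohort can be regenerated byte-identically).
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(
    list(planted_pairs = cohort$truth$planted_pairs,
         latent_risk = as.list(cohort$truth$latent_risk),
         planted_de_genes = cohort$truth$planted_de_genes,
         config = cohort$truth$config),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
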