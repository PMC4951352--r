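three_pair_sig <- function() {
  reo_signature(data.frame(
    gene_a = c("g1", "g3", "g5"), gene_b = c("g2", "g4", "g6"),
    high_risk_reo = c("lt", "lt", "gt"), stringsAsFactors = FALSE))
}

# expression matrix realizing a given vote pattern for three_pair_sig()
vote_expr <- function(votes) {  # list of logical length-3 vectors per sample
  n <- length(votes)
  m <- matrix(0, nrow = 6, ncol = n,
              dimnames = list(paste0("g", 1:6), paste0("s", seq_len(n))))
  for (j in seq_len(n)) {
    v <- votes[[j]]
    m[1, j] <- if (v[1]) 1 else 2; m[2, j] <- 1.5        # lt votes high
    m[3, j] <- if (v[2]) 3 else 4; m[4, j] <- 3.5
    m[5, j] <- if (v[3]) 6 else 5; m[6, j] <- 5.5        # gt votes high
  }
  m
}

test_that("majority vote follows the at-least-two-of-three rule", {
  sig <- three_pair_sig()
  expect_equal(sig$vote_threshold, 2L)
  m <- vote_expr(list(c(TRUE, TRUE, FALSE),   # H H L -> high
                      c(TRUE, FALSE, FALSE),  # H L L -> low
                      c(FALSE, FALSE, FALSE), # L L L -> low
                      c(TRUE, TRUE, TRUE)))   # H H H -> high
  calls <- classify_gps(m, sig)
  expect_equal(calls$label, c("high", "low", "low", "high"))
  expect_equal(calls$votes_high, c(2L, 1L, 0L, 3L))
})

test_that("exact expression ties never vote for high risk", {
  sig <- reo_signature(data.frame(gene_a = "g1", gene_b = "g2",
                                  high_risk_reo = "lt"))
  m <- matrix(c(1, 1), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(classify_gps(m, sig)$label, "low")
})

test_that("classification is invariant to cohort composition and monotone transforms", {
  set.seed(71)
  m <- make_expr(6, 40, seed = 71)
  rownames(m) <- paste0("g", 1:6)
  sig <- three_pair_sig()
  full <- classify_gps(m, sig)
  # single-sample invariance: each sample alone gets the same label
  for (s in colnames(m)[c(1, 13, 40)]) {
    solo <- classify_gps(m[, s, drop = FALSE], sig)
    expect_identical(solo$label, full$label[full$sample_id == s])
  }
  # arbitrary subsetting
  sub <- classify_gps(m, sig, samples = colnames(m)[c(5, 10, 20)])
  expect_identical(sub$label, full$label[c(5, 10, 20)])
  # strictly increasing per-sample transforms leave every call bit-identical
  for (seed in 1:5) {
    distorted <- classify_gps(monotone_distort(m, seed = seed), sig)
    expect_identical(distorted, full)
  }
})

test_that("missing signature genes are reported by name", {
  m <- make_expr(4, 3)
  sig <- three_pair_sig()
  expect_error(classify_gps(m, sig), "g1")
})

test_that("percentile voting flags directional tails over the analyzed samples", {
  m <- matrix(1:10, nrow = 1, dimnames = list("gX", paste0("s", 1:10)))
  genes <- data.frame(gene_id = "gX", risky_when = "high",
                      stringsAsFactors = FALSE)
  calls <- percentile_vote_classify(m, genes, vote_min = 1)
  cut <- quantile(1:10, 0.8)  # oracle percentile
  expect_identical(calls$label == "high", as.vector(m[1, ] > cut))
  # low-expression-risky direction
  genes_lo <- data.frame(gene_id = "gX", risky_when = "low",
                         stringsAsFactors = FALSE)
  calls_lo <- percentile_vote_classify(m, genes_lo, vote_min = 1)
  expect_identical(calls_lo$label == "high",
                   as.vector(m[1, ] < quantile(1:10, 0.2)))
  # identical values for all samples: nothing is flagged
  m2 <- matrix(5, nrow = 1, ncol = 6,
               dimnames = list("gX", paste0("s", 1:6)))
  expect_true(all(percentile_vote_classify(m2, genes, 1)$label == "low"))
  expect_error(percentile_vote_classify(m, genes, vote_min = 2), "vote_min")
})

test_that("percentile voting is unstable under reanalysis of its own low-risk calls", {
  # skewed tail: percentile cutoffs move when the extremes are removed
  vals <- c(1:16, 30, 40, 50, 60)
  m <- matrix(vals, nrow = 1,
              dimnames = list("gX", sprintf("s%02d", 1:20)))
  genes <- data.frame(gene_id = "gX", risky_when = "high",
                      stringsAsFactors = FALSE)
  first <- percentile_vote_classify(m, genes, vote_min = 1)
  low_ids <- first$sample_id[first$label == "low"]
  second <- percentile_vote_classify(m, genes, vote_min = 1,
                                     samples = low_ids)
  reclassified <- second$sample_id[second$label == "high"]
  expect_gt(length(reclassified), 0)
  # while the REO classifier never reclassifies under the same operation
  sig <- reo_signature(data.frame(gene_a = "gX", gene_b = "gY",
                                  high_risk_reo = "gt"))
  m2 <- rbind(m, gY = rep(15, 20))
  rcalls <- classify_gps(m2, sig)
  rlow <- rcalls$sample_id[rcalls$label == "low"]
  again <- classify_gps(m2, sig, samples = rlow)
  expect_true(all(again$label == "low"))
})

test_that("prognostic_pairs orients planted pairs and respects the partition guard", {
  cfg <- synthetic_config(n_genes = 120L, n_stage1 = 10L,
                          n_stage2_noctx = 200L, n_stage2_ctx = 0L,
                          n_stage34 = 10L, n_planted_pairs = 3L,
                          n_de_genes = 10L, hr_true = 4, seed = 5L)
  co <- generate_cohort(cfg)
  ii <- select_cohort(co$clinical, "II", ctx = FALSE)
  clin <- co$clinical[match(ii, co$clinical$sample_id), ]
  pp <- suppressWarnings(
    prognostic_pairs(co$expr, clin, co$truth$planted_pairs,
                     p_threshold = 0.01))
  expect_gt(nrow(pp), 0)
  # high-risk ordering recovered as planted (Ea < Eb, canonical order)
  expect_true(all(pp$high_risk_reo == "lt"))
  expect_true(all(pp$cox_hr > 1))
})

test_that("monotone-likelihood separation falls back to the score test", {
  # balanced partition: one group all early events, other all censored late
  n <- 16
  expr <- matrix(0, nrow = 2, ncol = n,
                 dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:n)))
  expr["gA", 1:8] <- 2; expr["gB", 1:8] <- 1    # group gt
  expr["gA", 9:n] <- 1; expr["gB", 9:n] <- 2    # group lt
  clin <- data.frame(sample_id = colnames(expr), stage = "II", ctx = 0,
                     rfs_time = c(1:8, rep(100, 8)),
                     rfs_event = c(rep(1L, 8), rep(0L, 8)),
                     stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = "gA", gene_b = "gB", stringsAsFactors = FALSE)
  expect_warning(
    pp <- prognostic_pairs(expr, clin, pairs, p_threshold = 0.01,
                           min_group_frac = 0.25),
    "monotone")
  expect_equal(nrow(pp), 1)              # retained via score-test fallback
  expect_equal(pp$high_risk_reo, "gt")   # events all sit in the gt group
})

test_that("degenerate partitions are skipped with a message", {
  n <- 20
  expr <- matrix(c(rep(2, n), rep(1, n)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:n)))
  clin <- data.frame(sample_id = colnames(expr), stage = "II", ctx = 0,
                     rfs_time = rexp(n) + 1, rfs_event = rep(1L, n),
                     stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = "gA", gene_b = "gB", stringsAsFactors = FALSE)
  expect_message(pp <- prognostic_pairs(expr, clin, pairs), "skipped")
  expect_equal(nrow(pp), 0)
})

test_that("forward selection returns the seed alone when nothing improves it", {
  # one strongly prognostic pair + 10 null pairs at n = 150
  set.seed(83)
  n <- 150
  expr <- make_expr(22, n, seed = 83)
  rownames(expr) <- paste0("g", 1:22)
  ids <- colnames(expr)
  risk <- rbinom(n, 1, 0.4)
  # pair g1/g2: REO tracks risk almost perfectly
  expr["g1", ] <- 8 + ifelse(risk == 1, -1.5, 1.5) + rnorm(n, 0, 0.2)
  expr["g2", ] <- 8 + rnorm(n, 0, 0.2)
  tm <- rexp(n, 0.01 * 6^risk)
  ev <- as.integer(tm <= rexp(n, 0.02))
  tm <- pmin(tm, rexp(n, 0.02)) + 1e-3
  clin <- data.frame(sample_id = ids, stage = "II", ctx = 0,
                     rfs_time = tm, rfs_event = ev, stringsAsFactors = FALSE)
  cand <- data.frame(gene_a = paste0("g", seq(1, 21, 2)),
                     gene_b = paste0("g", seq(2, 22, 2)),
                     high_risk_reo = "lt", cox_hr = 2,
                     stringsAsFactors = FALSE)
  sig <- forward_select(cand, expr, clin)
  expect_equal(pair_keys(sig$pairs)[1], "g1 g2")
  expect_equal(sig$vote_threshold, nrow(sig$pairs) %/% 2 + 1)
  # single candidate: signature of size 1, threshold 1
  sig1 <- forward_select(cand[1, ], expr, clin)
  expect_equal(nrow(sig1$pairs), 1)
  expect_equal(sig1$vote_threshold, 1L)
})

test_that("a three-pair planted signature classifies the default cohort accurately", {
  co <- default_cohort()
  sig <- reo_signature(co$truth$planted_pairs[1:3, ])
  ids <- select_cohort(co$clinical, "II", ctx = FALSE)
  calls <- classify_gps(co$expr, sig, ids)
  agreement <- mean((calls$label == "high") ==
                      (co$truth$latent_risk[ids] == "high"))
  # three pairs at 0.9 per-pair orientation fidelity, majority of 2:
  # expected accuracy ~ 0.97
  expect_gte(agreement, 0.9)
})

test_that("signatures round-trip through JSON and validate their votes", {
  sig <- three_pair_sig()
  f <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, f)
  back <- read_signature(f)
  expect_equal(back$pairs$gene_a, sig$pairs$gene_a)
  expect_equal(back$vote_threshold, sig$vote_threshold)
  expect_error(reo_signature(data.frame(gene_a = "x", gene_b = "x",
                                        high_risk_reo = "lt")), "repeat")
  expect_error(reo_signature(sig$pairs, vote_threshold = 5), "range")
})

test_that("the published three-pair signature loads with its voting rule", {
  sig <- gps3_signature()
  expect_equal(nrow(sig$pairs), 3)
  expect_equal(sig$vote_threshold, 2L)
  expect_setequal(sig$pairs$gene_a, c("ORC1", "MTNR1A", "RFX5"))
  expect_true(all(sig$pairs$high_risk_reo == "lt"))
  # classify a two-sample matrix over the published genes
  genes <- c(sig$pairs$gene_a, sig$pairs$gene_b)
  m <- matrix(c(1, 2, 1, 2, 1, 2,   # all three pairs vote high
                2, 1, 2, 1, 2, 1),  # none vote high
              ncol = 2, dimnames = list(genes, c("p1", "p2")))
  calls <- classify_gps(m, sig)
  expect_equal(calls$label, c("high", "low"))
})
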