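test_that("row t-test matches stats::t.test to high precision", {
  set.seed(17)
  m <- make_expr(30, 10)
  g1 <- colnames(m)[1:5]; g2 <- colnames(m)[6:10]
  res <- de_genes(m, g1, g2, all_genes = TRUE)
  for (g in rownames(m)[c(1, 7, 30)]) {
    tt <- t.test(m[g, g1], m[g, g2], var.equal = TRUE)
    row <- res[res$gene_id == g, ]
    expect_equal(row$t_statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
  # Welch variant
  resw <- de_genes(m, g1, g2, all_genes = TRUE, var_equal = FALSE)
  ttw <- t.test(m[1, g1], m[1, g2])
  expect_equal(resw$p_value[resw$gene_id == rownames(m)[1]], ttw$p.value,
               tolerance = 1e-10)
})

test_that("constant genes are never significant and groups are validated", {
  m <- make_expr(5, 8)
  m[1, ] <- 3.14
  g1 <- colnames(m)[1:4]; g2 <- colnames(m)[5:8]
  res <- de_genes(m, g1, g2, fdr_threshold = 1)
  expect_false(rownames(m)[1] %in% res$gene_id)
  all_res <- de_genes(m, g1, g2, all_genes = TRUE)
  expect_equal(all_res$p_value[all_res$gene_id == rownames(m)[1]], 1)
  expect_true(all(all_res$fdr >= all_res$p_value))
  expect_error(de_genes(m, g1, c(g1[1], g2)), "overlap")
  expect_error(de_genes(m, g1[1], g2), ">= 2")
})

test_that("de_genes recovers planted shift genes with correct directions", {
  co <- default_cohort()
  met <- select_cohort(co$clinical, c("III", "IV"))
  s1 <- select_cohort(co$clinical, "I")
  res <- de_genes(co$expr, met, s1, fdr_threshold = 0.1)
  planted <- co$truth$planted_de_genes
  hits <- intersect(planted, res$gene_id)
  expect_gte(length(hits) / length(planted), 0.9)
  # group1 = metastatic carries the +1 shift: every direction is "up"
  expect_true(all(res$direction[res$gene_id %in% hits] == "up"))
})

test_that("reo_frequency counts strict orderings with the tie rule", {
  m <- matrix(c(5, 3, 6, 2, 4, 4), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_equal(reo_frequency(m, c("a", "b")), 2 / 3)  # tie in s3 not counted
  m2 <- matrix(rep(1, 6), nrow = 2, dimnames = dimnames(m))
  expect_equal(reo_frequency(m2, c("a", "b")), 0)     # all ties -> 0
  # random fixture vs naive loop
  m3 <- make_expr(4, 20, seed = 23)
  cnt <- 0
  for (s in colnames(m3)) if (m3[1, s] > m3[2, s]) cnt <- cnt + 1
  expect_equal(reo_frequency(m3, rownames(m3)[1:2]), cnt / 20)
  expect_error(reo_frequency(m3, c("nope", rownames(m3)[1])), "nope")
})

test_that("pair Fisher p matches fisher.test and an enumeration oracle", {
  # extreme reversal 10/10 vs 0/10: p = 2 / C(20,10)
  p <- reosig:::fisher_p_2x2(10L, 0L, 10L, 10L)
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(p, fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-10)

  # random tables vs fisher.test and vs factorial enumeration
  set.seed(33)
  n1 <- 13L; n2 <- 9L
  for (rep in 1:25) {
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    p_pkg <- reosig:::fisher_p_2x2(a, b, n1, n2)
    tab <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    expect_equal(p_pkg, fisher.test(tab)$p.value, tolerance = 1e-9)
    # enumeration oracle with explicit factorials over all tables with the
    # observed margins
    m <- a + b
    prob_table <- function(x) {
      exp(lfactorial(m) - lfactorial(x) - lfactorial(m - x) +
          lfactorial(n1 + n2 - m) - lfactorial(n1 - x) -
          lfactorial(n2 - m + x) -
          (lfactorial(n1 + n2) - lfactorial(n1) - lfactorial(n2)))
    }
    supp <- max(0, m - n2):min(m, n1)
    probs <- vapply(supp, prob_table, numeric(1))
    p_oracle <- sum(probs[probs <= probs[supp == a] * (1 + 1e-7)])
    expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  }
})

test_that("reversed_pairs screens a small constructed fixture correctly", {
  # 2 genes reversed between groups + 2 null genes; 12 samples per group
  set.seed(41)
  n <- 12
  expr <- matrix(rnorm(4 * 2 * n, 8), nrow = 4,
                 dimnames = list(c("gA", "gB", "gC", "gD"),
                                 sprintf("s%02d", 1:(2 * n))))
  g1 <- sprintf("s%02d", 1:n); g2 <- sprintf("s%02d", (n + 1):(2 * n))
  # force gA > gB in group 1, gA < gB in group 2
  expr["gA", g1] <- expr["gB", g1] + abs(rnorm(n)) + 0.1
  expr["gA", g2] <- expr["gB", g2] - abs(rnorm(n)) - 0.1
  rp <- reversed_pairs(expr, g1, g2, candidate_genes = "gA",
                       fdr_threshold = 0.2)
  expect_true("gA\tgB" %in% paste(rp$gene_a, rp$gene_b, sep = "\t"))
  row <- rp[rp$gene_a == "gA" & rp$gene_b == "gB", ]
  expect_equal(row$freq1, 1)
  expect_equal(row$freq2, 0)
  expect_equal(row$direction, 1)
  expect_equal(row$fisher_p, 2 / choose(24, 12), tolerance = 1e-10)
})

test_that("identical orientation counts give p = 1 and are never retained", {
  # equal ordering counts in both groups: the central table has maximal
  # probability, so the two-sided tail is the whole distribution
  expect_equal(reosig:::fisher_p_2x2(4L, 4L, 8L, 8L), 1)
  m <- make_expr(6, 16, seed = 55)
  g1 <- colnames(m)[1:8]; g2 <- colnames(m)[9:16]
  # make gene 1 vs gene 2 orderings identical in both groups
  m[1, ] <- m[2, ] + rep(c(1, -1), 8)
  rp <- reversed_pairs(m, g1, g2, rownames(m)[1], fdr_threshold = 0.999)
  expect_false(nrow(rp) > 0 &&
                 any(rp$gene_a == rownames(m)[1] & rp$gene_b == rownames(m)[2]))
})

test_that("reversal screen is invariant under per-sample monotone transforms", {
  m <- make_expr(12, 30, seed = 61)
  g1 <- colnames(m)[1:15]; g2 <- colnames(m)[16:30]
  m[1, g1] <- m[2, g1] + 1   # plant one reversal
  m[1, g2] <- m[2, g2] - 1
  rp1 <- reversed_pairs(m, g1, g2, rownames(m)[1:3], fdr_threshold = 1)
  rp2 <- reversed_pairs(monotone_distort(m), g1, g2, rownames(m)[1:3],
                        fdr_threshold = 1)
  expect_equal(rp1, rp2)
})

test_that("consistent_overlap matches pairs, counts directions, and drops discordant pairs", {
  la <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                   freq1 = c(0.9, 0.8, 0.7), freq2 = c(0.1, 0.2, 0.9),
                   fisher_p = 1e-4, fdr = 1e-3,
                   direction = c(1, 1, -1), stringsAsFactors = FALSE)
  # identical lists: all survive with score 1
  ov <- consistent_overlap(la, la)
  expect_equal(ov$score, 1)
  expect_equal(nrow(ov$survivors), 3)

  # one direction flipped in list B: dropped from survivors
  lb <- la; lb$direction[2] <- -1
  ov2 <- consistent_overlap(la, lb)
  expect_equal(ov2$k, 3L); expect_equal(ov2$s, 2L)
  expect_equal(ov2$score, 2 / 3)
  expect_setequal(pair_keys(ov2$survivors), c("a b", "e f"))

  # published-scale counts: 6377 of 6386 consistent -> 99.86%
  expect_equal(round(100 * 6377 / 6386, 2), 99.86)

  # disjoint lists: k = 0, score not applicable
  lc <- la; lc$gene_a <- c("x", "y", "z"); lc$gene_b <- c("x2", "y2", "z2")
  ov3 <- consistent_overlap(la, lc)
  expect_identical(ov3$k, 0L)
  expect_true(is.na(ov3$score))
  expect_equal(nrow(ov3$survivors), 0)
})
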