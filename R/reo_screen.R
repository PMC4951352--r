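#' Two-group differential expression by row-wise t-test
#'
#' Student's two-sided t-test per gene between two disjoint sample groups,
#' with Benjamini-Hochberg adjustment over all tested genes. The default is
#' the pooled-variance (equal-variance) form; Welch's unequal-variance form
#' is available via `var_equal = FALSE`. The test is computed with a
#' vectorized row-wise implementation for speed; it is numerically
#' identical to [stats::t.test()] on each row.
#'
#' Genes constant in both groups carry no information and are assigned
#' p = 1 (they can never be returned as significant).
#'
#' @param expr Expression matrix (genes x samples, log2 scale).
#' @param group1,group2 Disjoint character vectors of sample identifiers,
#'   each of size >= 2. `direction` is "up" when the group-1 mean exceeds
#'   the group-2 mean.
#' @param fdr_threshold Retain genes with BH-adjusted p below this value
#'   (default 0.1).
#' @param var_equal Pooled-variance Student form (default) or Welch.
#' @param all_genes Return every tested gene instead of the significant
#'   subset.
#' @return data.frame with columns `gene_id`, `t_statistic`, `p_value`,
#'   `fdr`, `direction`, ordered by p-value.
#' @export
de_genes <- function(expr, group1, group2, fdr_threshold = 0.1,
                     var_equal = TRUE, all_genes = FALSE) {
  validate_expression(expr)
  if (length(intersect(group1, group2)) > 0L)
    stop("group1 and group2 overlap")
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs >= 2 samples")
  missing_s <- setdiff(c(group1, group2), colnames(expr))
  if (length(missing_s) > 0L)
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 5L),
                                         collapse = ", "))
  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  flat <- se == 0
  tstat[flat & m1 == m2] <- 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, 0)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(expr),
                    t_statistic = tstat,
                    p_value = p,
                    fdr = fdr,
                    direction = ifelse(m1 >= m2, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!all_genes) out <- out[out$fdr < fdr_threshold, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Within-sample relative ordering frequency of a gene pair
#'
#' Fraction of the listed samples in which the first gene's value strictly
#' exceeds the second gene's (Ea > Eb). Ties count as "not greater": the
#' rule is deterministic and conservative, and ties have probability zero
#' for continuous intensities.
#'
#' @param expr Expression matrix.
#' @param pair Length-2 character vector `(gene_a, gene_b)`.
#' @param samples Sample identifiers over which to compute the frequency.
#' @return Frequency in `[0, 1]`.
#' @export
reo_frequency <- function(expr, pair, samples = colnames(expr)) {
  validate_expression(expr)
  if (length(pair) != 2L) stop("pair must name exactly two genes")
  missing_g <- setdiff(pair, rownames(expr))
  if (length(missing_g) > 0L)
    stop("unknown gene id(s): ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(samples, colnames(expr))
  if (length(missing_s) > 0L)
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 5L),
                                         collapse = ", "))
  mean(expr[pair[1L], samples] > expr[pair[2L], samples])
}

# Two-sided Fisher exact p for the 2x2 table
#   [a, n1 - a; b, n2 - b]
# (a, b = per-group counts of the Ea > Eb ordering). Two-sided by the
# standard rule: sum the probabilities of all tables with the observed
# margins whose hypergeometric probability does not exceed the observed
# table's (up to a relative tolerance for floating-point equality).
# Vectorized over (a, b) with memoization over distinct tables; the pair
# screen evaluates ~1e5 tables with only O(n1 * n2) distinct ones.
#' @keywords internal
fisher_p_2x2 <- function(a, b, n1, n2) {
  m <- a + b
  key <- paste(a, m, sep = ":")
  uk <- !duplicated(key)
  p_unique <- vapply(which(uk), function(i) {
    mi <- m[i]
    lo <- max(0L, mi - n2); hi <- min(mi, n1)
    supp <- lo:hi
    d <- stats::dhyper(supp, mi, n1 + n2 - mi, n1)
    pobs <- d[supp == a[i]]
    min(1, sum(d[d <= pobs * (1 + 1e-7)]))
  }, numeric(1))
  p_unique[match(key, key[uk])]
}

#' @keywords internal
canonical_pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\t")
}

#' Screen gene pairs for reversed relative orderings between two groups
#'
#' For every unordered gene pair with at least one member in
#' `candidate_genes` (both members measured), the frequency of the
#' Ea > Eb ordering is compared between the two sample groups by a
#' two-sided Fisher exact test on the 2x2 table of ordering counts, with
#' Benjamini-Hochberg adjustment over all tested pairs. Pairs with
#' adjusted p below `fdr_threshold` are returned.
#'
#' Pairs are canonicalized so that `gene_a < gene_b` lexicographically;
#' `direction` is the sign of `freq1 - freq2` under that orientation.
#' Because only within-sample orderings enter the counts, the result is
#' invariant under any strictly increasing per-sample transform of the
#' expression values.
#'
#' @param expr Expression matrix.
#' @param group1,group2 Disjoint sample-id vectors (e.g. metastatic vs
#'   non-metastatic samples).
#' @param candidate_genes Non-empty gene set anchoring the pair universe
#'   (typically the differentially expressed genes).
#' @param fdr_threshold BH-FDR cutoff (default 0.2).
#' @return data.frame with columns `gene_a`, `gene_b`, `freq1`, `freq2`,
#'   `fisher_p`, `fdr`, `direction`, ordered by p.
#' @export
reversed_pairs <- function(expr, group1, group2, candidate_genes,
                           fdr_threshold = 0.2) {
  validate_expression(expr)
  if (length(candidate_genes) == 0L) stop("candidate_genes is empty")
  if (length(intersect(group1, group2)) > 0L)
    stop("group1 and group2 overlap")
  candidate_genes <- intersect(unique(candidate_genes), rownames(expr))
  if (length(candidate_genes) == 0L)
    stop("no candidate gene is measured: empty pair universe")
  genes <- rownames(expr)
  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  is_cand <- genes %in% candidate_genes
  cand_rank <- match(genes, sort(candidate_genes))  # NA for non-candidates

  rows <- vector("list", length(candidate_genes))
  for (ci in seq_along(candidate_genes)) {
    cg <- candidate_genes[ci]
    # count per partner gene g of samples with E_cg > E_g, per group
    gt1 <- rowSums(sweep(x1, 2L, x1[cg, ], `<`))
    gt2 <- rowSums(sweep(x2, 2L, x2[cg, ], `<`))
    # partner counts in the opposite orientation (tie-safe: ties count for
    # neither gene)
    lt1 <- rowSums(sweep(x1, 2L, x1[cg, ], `>`))
    lt2 <- rowSums(sweep(x2, 2L, x2[cg, ], `>`))
    # dedupe: keep partner if non-candidate, or candidate with higher rank
    crank <- cand_rank[match(cg, genes)]
    keep <- genes != cg & (!is_cand | (!is.na(cand_rank) & cand_rank > crank))
    partner <- genes[keep]
    first_is_c <- cg < partner  # canonical gene_a
    rows[[ci]] <- data.frame(
      gene_a = ifelse(first_is_c, cg, partner),
      gene_b = ifelse(first_is_c, partner, cg),
      a1 = ifelse(first_is_c, gt1[keep], lt1[keep]),
      a2 = ifelse(first_is_c, gt2[keep], lt2[keep]),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$fisher_p <- fisher_p_2x2(tab$a1, tab$a2, n1, n2)
  tab$fdr <- stats::p.adjust(tab$fisher_p, method = "BH")
  tab$freq1 <- tab$a1 / n1
  tab$freq2 <- tab$a2 / n2
  tab$direction <- sign(tab$freq1 - tab$freq2)
  out <- tab[tab$fdr < fdr_threshold,
             c("gene_a", "gene_b", "freq1", "freq2",
               "fisher_p", "fdr", "direction")]
  rownames(out) <- NULL
  out[order(out$fisher_p), , drop = FALSE]
}

#' Cross-dataset consistency filter for reversed gene pairs
#'
#' Matches two reversal lists as unordered gene pairs and keeps, as the
#' surviving set, the overlapped pairs whose reversal direction agrees in
#' both datasets. Reports the overlap count `k`, the same-direction count
#' `s`, and the consistency score `s/k` (NA when `k` is 0).
#'
#' @param list_a,list_b data.frames from [reversed_pairs()].
#' @return list with `k`, `s`, `score`, `overlap` (merged records) and
#'   `survivors` (the same-direction subset of `list_a`'s records).
#' @export
consistent_overlap <- function(list_a, list_b) {
  key_a <- canonical_pair_key(list_a$gene_a, list_a$gene_b)
  key_b <- canonical_pair_key(list_b$gene_a, list_b$gene_b)
  hit <- match(key_a, key_b)
  in_both <- !is.na(hit)
  k <- sum(in_both)
  if (k == 0L)
    return(list(k = 0L, s = 0L, score = NA_real_,
                overlap = list_a[0, , drop = FALSE],
                survivors = list_a[0, , drop = FALSE]))
  same <- in_both & list_a$direction == list_b$direction[hit]
  s <- sum(same)
  overlap <- list_a[in_both, , drop = FALSE]
  overlap$direction_b <- list_b$direction[hit[in_both]]
  survivors <- list_a[same, , drop = FALSE]
  rownames(overlap) <- rownames(survivors) <- NULL
  list(k = k, s = s, score = s / k, overlap = overlap, survivors = survivors)
}
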