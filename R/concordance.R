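#' Binomial concordance score of two directed gene lists
#'
#' Given two lists of differentially expressed items (genes or gene pairs)
#' with a direction attached to each, let `k` be the number of overlapped
#' items and `s` the number whose directions agree. The concordance score
#' is `s/k`, and its chance probability is the upper-tail cumulative
#' binomial
#' \deqn{P = 1 - \sum_{i=0}^{s-1} \binom{k}{i} P_e^i (1-P_e)^{k-i},}
#' with `Pe` the per-item chance agreement probability (1/2 when two
#' directions are equally likely). The tail is computed in log space, so
#' very small probabilities (k in the hundreds) are exact; `log_p` is
#' reported alongside for values below double precision.
#'
#' Either supply two named direction vectors (names = item identifiers,
#' values = directions such as `"up"`/`"down"`), or supply `k` and `s`
#' directly.
#'
#' @param list_a,list_b Named character vectors mapping item -> direction.
#' @param k,s Overlap and same-direction counts, as an alternative to the
#'   two lists.
#' @param pe Chance agreement probability (default 0.5).
#' @return list with `k`, `s`, `score`, `pe`, `p_value`, `log_p`. With
#'   `k = 0` the score and p-value are `NA` (not applicable).
#' @export
concordance_score <- function(list_a = NULL, list_b = NULL,
                              k = NULL, s = NULL, pe = 0.5) {
  if (is.null(k)) {
    if (is.null(list_a) || is.null(list_b))
      stop("supply either two directed lists or counts k and s")
    common <- intersect(names(list_a), names(list_b))
    k <- length(common)
    s <- sum(list_a[common] == list_b[common])
  }
  if (s > k || s < 0) stop("require 0 <= s <= k")
  if (pe <= 0 || pe >= 1) stop("pe must be in (0, 1)")
  if (k == 0L)
    return(list(k = 0L, s = 0L, score = NA_real_, pe = pe,
                p_value = NA_real_, log_p = NA_real_))
  log_p <- stats::pbinom(s - 1, k, pe, lower.tail = FALSE, log.p = TRUE)
  list(k = as.integer(k), s = as.integer(s), score = s / k, pe = pe,
       p_value = exp(log_p), log_p = log_p)
}

#' Hypergeometric overlap test of two gene sets
#'
#' Upper-tail probability of observing at least the realized overlap
#' between two gene sets drawn from a universe of `universe_size` genes.
#'
#' @param set_a,set_b Character vectors of gene identifiers (duplicates
#'   ignored).
#' @param universe_size Number of genes in the universe; must be at least
#'   the size of each set.
#' @return list with `overlap`, `n_a`, `n_b`, `universe_size`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe_size < length(set_a) || universe_size < length(set_b))
    stop("universe smaller than one of the sets")
  m <- length(intersect(set_a, set_b))
  p <- stats::phyper(m - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = m, n_a = length(set_a), n_b = length(set_b),
       universe_size = universe_size, p_value = p)
}

#' Read gene categories in GMT format
#'
#' Standard tab-separated gene-set format: set name, description, then the
#' member genes. Parsed with [fgsea::gmtPathways()].
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric category enrichment of a DE gene list
#'
#' For each category the test asks whether the number of DE genes
#' annotated to it exceeds chance expectation. With `N` the measured genes
#' carrying any annotation, `n` the DE genes among them, `M` the measured
#' genes in the category and `m` the DE genes in the category, the
#' upper-tail probability is
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{n}{i}\binom{N-n}{M-i} / \binom{N}{M}.}
#' Categories are intersected with the measured genes before counting, and
#' p-values are Benjamini-Hochberg adjusted across all tested categories.
#'
#' @param de_genes Character vector of DE gene identifiers.
#' @param categories Named list of gene vectors (see [read_gmt()]).
#' @param measured_genes Character vector of all measured genes.
#' @param fdr_threshold Adjusted-p cutoff for the `significant` flag
#'   (default 0.05).
#' @return data.frame with columns `category`, `N`, `n`, `M`, `m`,
#'   `p_value`, `adjusted_p`, `significant`, ordered by p.
#' @export
enrich_categories <- function(de_genes, categories, measured_genes,
                              fdr_threshold = 0.05) {
  measured_genes <- unique(measured_genes)
  de_genes <- intersect(unique(de_genes), measured_genes)
  cats <- lapply(categories, intersect, measured_genes)
  cats <- cats[lengths(cats) > 0L]
  if (length(cats) == 0L)
    stop("no category overlaps the measured genes")
  annotated <- unique(unlist(cats))
  N <- length(annotated)
  n <- length(intersect(de_genes, annotated))
  M <- lengths(cats)
  m <- vapply(cats, function(g) length(intersect(de_genes, g)), integer(1))
  p <- stats::phyper(m - 1, n, N - n, M, lower.tail = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(category = names(cats), N = N, n = n, M = M, m = m,
                    p_value = p, adjusted_p = adj,
                    significant = adj < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Consensus of differentially expressed gene lists across datasets
#'
#' Integrates per-dataset DE tables into one list by the rule: keep genes
#' significant in at least `min_datasets` of the lists, after excluding any
#' gene whose direction disagrees between any two lists in which it
#' appears.
#'
#' @param de_list List of data.frames with columns `gene_id`, `direction`
#'   (as returned by [de_genes()]).
#' @param min_datasets Minimum number of lists a gene must appear in
#'   (default 2).
#' @return data.frame with columns `gene_id`, `direction`, `n_datasets`.
#' @export
consensus_de <- function(de_list, min_datasets = 2L) {
  if (length(de_list) < min_datasets)
    stop("fewer lists than min_datasets")
  all_genes <- unlist(lapply(de_list, `[[`, "gene_id"))
  tab <- table(all_genes)
  cand <- names(tab)[tab >= min_datasets]
  dirs <- lapply(de_list, function(d)
    stats::setNames(d$direction, d$gene_id))
  keep <- character(0); dir_out <- character(0); n_out <- integer(0)
  for (g in cand) {
    dg <- unlist(lapply(dirs, function(d) d[g]))
    dg <- dg[!is.na(dg)]
    if (length(unique(dg)) == 1L) {
      keep <- c(keep, g)
      dir_out <- c(dir_out, dg[1L])
      n_out <- c(n_out, length(dg))
    }
  }
  data.frame(gene_id = keep, direction = dir_out, n_datasets = n_out,
             row.names = NULL, stringsAsFactors = FALSE)
}
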