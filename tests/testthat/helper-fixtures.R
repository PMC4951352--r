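# Shared fixtures, built in code at load time.

# Tiny deterministic expression matrix
make_expr <- function(n_genes = 10, n_samples = 6, seed = 42,
                      gene_prefix = "G") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, mean = 8, sd = 2),
              nrow = n_genes,
              dimnames = list(sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

# Clinical table with the stage/chemotherapy margins of a large CRC series:
# 33 stage I, 203 stage II without CTX, 56 stage II with CTX, 205 stage III,
# 60 stage IV.
make_margins_clinical <- function() {
  stage <- c(rep("I", 33), rep("II", 203 + 56), rep("III", 205), rep("IV", 60))
  ctx <- c(rep(0, 33), rep(0, 203), rep(1, 56), rep(0, 205), rep(0, 60))
  n <- length(stage)
  data.frame(sample_id = sprintf("P%04d", seq_len(n)),
             stage = stage, ctx = ctx,
             rfs_time = rep(10, n), rfs_event = rep(0L, n),
             stringsAsFactors = FALSE)
}

# Apply an independent random strictly increasing transform to each sample
# (a smooth monotone distortion mimicking a batch effect): scale, shift,
# and a monotone cube-law warp around the sample median.
monotone_distort <- function(expr, seed = 7) {
  set.seed(seed)
  out <- expr
  for (j in seq_len(ncol(expr))) {
    a <- stats::runif(1, 0.5, 2)
    b <- stats::rnorm(1, 0, 3)
    c3 <- stats::runif(1, 0, 0.05)
    v <- expr[, j]
    out[, j] <- a * v + b + c3 * (v - stats::median(v))^3
  }
  out
}

# Default synthetic cohort, generated once per test session (used by the
# recovery and acceptance tests).
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reosig::generate_cohort(
      reosig::synthetic_config(seed = 1L))
    cache
  }
})

pair_keys <- function(df) paste(df$gene_a, df$gene_b)
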