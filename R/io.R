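#' Read a log2 expression matrix from a tab-separated file
#'
#' The expected layout is the conventional genes-by-samples text matrix:
#' the first column holds gene (or probe) identifiers, the header row holds
#' sample identifiers, and every remaining cell is a numeric log2 intensity.
#' Values are assumed to be on the log2 scale throughout the package; only
#' within-sample orderings are ever used downstream, so no normalization is
#' expected or performed.
#'
#' Missing or non-numeric cells are rejected with their row/column position:
#' the relative ordering of a gene pair is undefined when either member is
#' missing, so imputation is deliberately not offered. Duplicate row
#' identifiers are an error at this layer; probe-level matrices must be
#' collapsed with [collapse_probes()] first.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames.
#' @seealso [write_expression()], [collapse_probes()]
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression file must have an identifier column plus >= 1 sample column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifiers in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) ", ..." else "")
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header of ", path)
  values <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) values <- matrix(values, nrow = 1L)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or missing expression value at gene '%s' (row %d), sample '%s' (column %d)",
      ids[bad[1L, 1L]], bad[1L, 1L], samples[bad[1L, 2L]], bad[1L, 2L] + 1L))
  }
  dimnames(values) <- list(ids, samples)
  validate_expression(values)
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: first column `gene_id`, then one column
#' per sample. Values are written with full double precision so that a
#' write/read round trip is numerically faithful.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr),
                   format(expr, trim = TRUE, digits = 15L, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers in expression matrix")
  if (!all(is.finite(expr)))
    stop("expression matrix contains non-finite values")
  invisible(expr)
}

#' Read a clinical annotation table
#'
#' Tab-separated, one row per sample. Required columns: `sample_id`,
#' `stage` (I/II/III/IV), `ctx` (0/1 adjuvant chemotherapy flag),
#' `rfs_time` (months, > 0), `rfs_event` (1 = relapse, 0 = censored).
#' Additional covariate columns (age, sex, msi, localization, mutation
#' flags, ...) are carried through unchanged; unknown categorical values
#' are encoded with the literal token `"unknown"` and handled casewise by
#' [cox_fit()]. Missing RFS annotations (`NA`) are tolerated here and
#' dropped, with a message, by [select_cohort()].
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with `ctx` as logical and `stage` as character.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Write a clinical table as tab-separated text
#' @param clinical Clinical `data.frame` as accepted by [validate_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  out$ctx <- as.integer(out$ctx)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a clinical table
#'
#' @param clinical A data.frame with at least the required columns (see
#'   [read_clinical()]).
#' @return The validated data.frame (ctx coerced to logical), invisibly
#'   usable in place.
#' @export
validate_clinical <- function(clinical) {
  required <- c("sample_id", "stage", "ctx", "rfs_time", "rfs_event")
  missing_cols <- setdiff(required, colnames(clinical))
  if (length(missing_cols) > 0L)
    stop("clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample_id in clinical table")
  ok_stage <- clinical$stage %in% c("I", "II", "III", "IV")
  if (!all(ok_stage))
    stop("invalid stage value(s): ",
         paste(unique(clinical$stage[!ok_stage]), collapse = ", "))
  if (!all(clinical$ctx %in% c(0, 1, TRUE, FALSE)))
    stop("ctx must be 0/1")
  clinical$ctx <- as.logical(clinical$ctx)
  has_rfs <- !is.na(clinical$rfs_time) & !is.na(clinical$rfs_event)
  if (any(clinical$rfs_time[has_rfs] <= 0))
    stop("rfs_time must be > 0")
  if (!all(clinical$rfs_event[has_rfs] %in% c(0, 1)))
    stop("rfs_event must be 0 or 1")
  clinical
}

#' Read a probe-to-gene mapping
#'
#' Two-column tab-separated file `probe_id`, `gene_id`; many probes may map
#' to one gene, but each probe must map to exactly one gene.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% colnames(df)))
    stop("probe map must have columns probe_id, gene_id")
  if (anyDuplicated(df$probe_id))
    stop("probe map assigns some probe to more than one gene: ",
         paste(utils::head(unique(df$probe_id[duplicated(df$probe_id)]), 5L),
               collapse = ", "))
  df
}

#' Collapse a probe-level matrix to gene level
#'
#' When several probes map to the same gene, the gene's expression is the
#' unweighted arithmetic mean of the probe rows on the log2 scale. Probes
#' absent from the map are dropped with a message reporting the count.
#'
#' @param probe_expr Numeric matrix keyed by probe identifiers.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`
#'   (see [read_probe_map()]).
#' @return Numeric matrix keyed by gene identifiers.
#' @export
collapse_probes <- function(probe_expr, probe_map) {
  validate_expression(probe_expr)
  if (anyDuplicated(probe_map$probe_id))
    stop("probe map assigns some probe to more than one gene")
  keep <- rownames(probe_expr) %in% probe_map$probe_id
  if (!any(keep))
    stop("no probe in the matrix is present in the probe map")
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " probe(s) absent from the probe map were dropped")
  sub <- probe_expr[keep, , drop = FALSE]
  gene <- probe_map$gene_id[match(rownames(sub), probe_map$probe_id)]
  sums <- rowsum(sub, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  validate_expression(out)
  out
}

#' Select an analysis cohort by tumor stage and chemotherapy status
#'
#' Returns the sample identifiers, in the clinical table's row order, of
#' samples matching the stage filter and chemotherapy filter. Samples with
#' missing RFS annotations are excluded with a message reporting the count,
#' since every downstream use of a cohort involves its survival outcome.
#'
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param stages Character vector of stages to retain, e.g. `c("II")`.
#' @param ctx One of `TRUE`, `FALSE`, or `"any"` (default).
#' @return Character vector of sample identifiers (possibly empty).
#' @export
select_cohort <- function(clinical, stages, ctx = "any") {
  clinical <- validate_clinical(clinical)
  bad <- setdiff(stages, c("I", "II", "III", "IV"))
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  keep <- clinical$stage %in% stages
  if (!identical(ctx, "any")) {
    if (!is.logical(ctx) || length(ctx) != 1L)
      stop("ctx must be TRUE, FALSE or \"any\"")
    keep <- keep & clinical$ctx == ctx
  }
  no_rfs <- is.na(clinical$rfs_time) | is.na(clinical$rfs_event)
  if (any(keep & no_rfs)) {
    message(sum(keep & no_rfs),
            " sample(s) dropped from cohort for missing RFS annotation")
    keep <- keep & !no_rfs
  }
  clinical$sample_id[keep]
}
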