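#' Construct an expression cohort
#'
#' Bundles a strictly positive, linear-scale gene-by-sample expression
#' matrix with its sample sheet and, optionally, the underlying
#' probe-level table. This is the container every analysis function in
#' the package consumes.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Linear scale, all
#'   values > 0 (NAs allowed for missing quantifications).
#' @param samples Data frame with columns `sample_id`, `sex`
#'   (`"male"`/`"female"`), `condition` (one of SNS, BNS, BYS, BYA,
#'   BYP) and `replica` (integer). One row per column of `values`.
#' @param probe_values Optional probe-by-sample matrix (same columns as
#'   `values`).
#' @param probe_map Optional data frame with columns `probe_id`,
#'   `gene_id` mapping each probe to at most one gene.
#' @param tech_cv Optional gene-by-sample matrix of technical CVs
#'   (across a gene's probes, per sample); filled in by
#'   [summarize_probes()].
#'
#' @return An object of class `ExpressionCohort`: a list with elements
#'   `values`, `samples`, and optionally `probe_values`, `probe_map`,
#'   `tech_cv`.
#' @export
expression_cohort <- function(values, samples, probe_values = NULL,
                              probe_map = NULL, tech_cv = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers: ",
         paste(head(unique(rownames(values)[duplicated(rownames(values))])),
               collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "sex", "condition", "replica")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample ids in sample sheet")
  missing_samples <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_samples))
    stop("sample sheet missing sample column(s): ",
         paste(missing_samples, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  bad_cond <- setdiff(unique(samples$condition), CONDITIONS)
  if (length(bad_cond))
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         " (expected ", paste(CONDITIONS, collapse = "/"), ")")
  key <- paste(samples$sex, samples$condition, samples$replica)
  if (anyDuplicated(key))
    stop("duplicated (sex, condition, replica) sample(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  neg <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("non-positive expression value at gene ",
         rownames(values)[neg[1, 1]], ", sample ",
         colnames(values)[neg[1, 2]],
         " (linear-scale values must be > 0)")
  structure(
    list(values = values, samples = samples, probe_values = probe_values,
         probe_map = probe_map, tech_cv = tech_cv),
    class = "ExpressionCohort")
}

#' @export
print.ExpressionCohort <- function(x, ...) {
  cat("ExpressionCohort:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  sexes:", paste(unique(x$samples$sex), collapse = ", "), "\n")
  cat("  conditions:",
      paste(intersect(CONDITIONS, unique(x$samples$condition)),
            collapse = ", "), "\n")
  if (!is.null(x$probe_values))
    cat("  probe table:", nrow(x$probe_values), "probes\n")
  invisible(x)
}

#' Read an expression cohort from delimited text
#'
#' @param expr_path Tab-delimited gene-by-sample table; first column
#'   `gene_id`, remaining columns one per sample.
#' @param sample_sheet_path Tab-delimited sample sheet with columns
#'   `sample_id`, `sex`, `condition`, `replica`.
#' @param probe_path,probe_map_path Optional probe-level table (first
#'   column `probe_id`) and probe-to-gene map (`probe_id`, `gene_id`).
#'
#' @return An [expression_cohort()].
#' @export
read_cohort <- function(expr_path, sample_sheet_path,
                        probe_path = NULL, probe_map_path = NULL) {
  expr <- read.delim(expr_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (names(expr)[1] != "gene_id")
    stop("expression table must start with a `gene_id` column, found `",
         names(expr)[1], "`")
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr$gene_id
  storage.mode(values) <- "double"
  samples <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  probe_values <- NULL
  probe_map <- NULL
  if (!is.null(probe_path)) {
    pt <- read.delim(probe_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    probe_values <- as.matrix(pt[, -1, drop = FALSE])
    rownames(probe_values) <- pt[[1]]
    storage.mode(probe_values) <- "double"
    if (is.null(probe_map_path))
      stop("probe table given without a probe map")
    probe_map <- read.delim(probe_map_path, stringsAsFactors = FALSE)
  }
  expression_cohort(values, samples, probe_values = probe_values,
                    probe_map = probe_map)
}

#' Write an expression cohort as delimited text
#'
#' Writes `expression.tsv` and `samples.tsv` (plus `probes.tsv` /
#' `probe_map.tsv` when a probe table is present) into `dir`. The files
#' round-trip through [read_cohort()].
#'
#' @param cohort An `ExpressionCohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"))
  expr <- data.frame(gene_id = rownames(cohort$values),
                     cohort$values, check.names = FALSE)
  write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort$probe_values)) {
    paths <- c(paths, probes = file.path(dir, "probes.tsv"),
               probe_map = file.path(dir, "probe_map.tsv"))
    pt <- data.frame(probe_id = rownames(cohort$probe_values),
                     cohort$probe_values, check.names = FALSE)
    write.table(pt, paths["probes"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(cohort$probe_map, paths["probe_map"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Summarize a probe-level table to gene level
#'
#' Each gene's value in a sample is the median of its probes' values
#' there (robust to single bad spots). The spread across a gene's
#' probes is retained as a per-gene, per-sample technical CV (sd/mean
#' of the probe set) and feeds the adaptive regulation cut-off.
#' Single-probe genes pass through with technical CV 0. Probes mapping
#' to no gene are dropped.
#'
#' @param probe_values Probe-by-sample numeric matrix (rownames =
#'   probe ids).
#' @param probe_map Data frame with columns `probe_id`, `gene_id`;
#'   every probe maps to at most one gene.
#' @return List with `values` (gene-by-sample medians) and `tech_cv`
#'   (gene-by-sample technical CVs).
#' @export
summarize_probes <- function(probe_values, probe_map) {
  if (is.null(probe_map) || nrow(probe_map) == 0)
    stop("empty probe map")
  if (anyDuplicated(probe_map$probe_id))
    stop("a probe maps to more than one gene")
  keep <- rownames(probe_values) %in% probe_map$probe_id
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " unmapped probe(s) dropped")
  pv <- probe_values[keep, , drop = FALSE]
  gene_of <- probe_map$gene_id[match(rownames(pv), probe_map$probe_id)]
  genes <- unique(gene_of)
  idx <- split(seq_len(nrow(pv)), factor(gene_of, levels = genes))
  n_probes <- lengths(idx)

  values <- matrix(NA_real_, length(genes), ncol(pv),
                   dimnames = list(genes, colnames(pv)))
  tech_cv <- matrix(0, length(genes), ncol(pv),
                    dimnames = list(genes, colnames(pv)))
  single <- n_probes == 1L
  if (any(single))
    values[single, ] <- pv[unlist(idx[single]), , drop = FALSE]
  for (g in which(!single)) {
    block <- pv[idx[[g]], , drop = FALSE]
    values[g, ] <- apply(block, 2, median, na.rm = TRUE)
    m <- colMeans(block, na.rm = TRUE)
    s <- apply(block, 2, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2) NA_real_ else sd(z)
    })
    tech_cv[g, ] <- ifelse(!is.na(m) & is.finite(m) & m > 0 & !is.na(s),
                           s / m, 0)
  }
  list(values = values, tech_cv = tech_cv)
}

#' Median-normalize each array
#'
#' Divides every array (column) by its own median so the per-array
#' median gene equals 1.0. This puts the mean expression levels that
#' weight the WPR score into dimensionless "array-median units", making
#' WPR comparable across arrays and O(1-10) in magnitude. The
#' operation is idempotent and removes any common per-array scale
#' factor. The probe table, if present, is divided by the same
#' per-array factors so probe-level technical CVs are unchanged.
#'
#' @param cohort An `ExpressionCohort`.
#' @return The normalized `ExpressionCohort`.
#' @export
normalize_median <- function(cohort) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  med <- apply(cohort$values, 2, median, na.rm = TRUE)
  if (any(!is.finite(med) | med <= 0))
    stop("array median not positive; cannot normalize")
  cohort$values <- sweep(cohort$values, 2, med, "/")
  if (!is.null(cohort$probe_values))
    cohort$probe_values <- sweep(cohort$probe_values, 2, med, "/")
  cohort
}

.sample_ids <- function(cohort, sex, condition) {
  sh <- cohort$samples
  ids <- sh$sample_id[sh$sex == sex & sh$condition == condition]
  if (!length(ids))
    stop("no samples for sex=", sex, ", condition=", condition)
  ids
}

#' Per-gene replica statistics within one condition
#'
#' Mean, standard deviation and coefficient of variation of each gene
#' over the biological replicas of one (sex, condition) cell, on the
#' linear scale. These are the \eqn{\mu} and CV inputs of the adaptive
#' cut-off and the WPR score. Missing values reduce the recorded `n`
#' for that gene.
#'
#' @param cohort An `ExpressionCohort`.
#' @param sex `"male"` or `"female"`.
#' @param condition One of SNS, BNS, BYS, BYA, BYP.
#' @return Data frame with columns `gene`, `mean`, `sd`, `cv`, `n`,
#'   plus `tech_cv` (mean technical CV over the condition's samples;
#'   0 when no probe table exists).
#' @export
condition_stats <- function(cohort, sex, condition) {
  ids <- .sample_ids(cohort, sex, condition)
  if (length(ids) < 2)
    stop("need >= 2 replicas for condition statistics (got ",
         length(ids), " for ", sex, "/", condition, ")")
  v <- cohort$values[, ids, drop = FALSE]
  n <- rowSums(!is.na(v))
  mu <- rowMeans(v, na.rm = TRUE)
  sdev <- apply(v, 1, sd, na.rm = TRUE)
  sdev[n < 2] <- NA_real_
  tech <- if (!is.null(cohort$tech_cv))
    rowMeans(cohort$tech_cv[rownames(v), ids, drop = FALSE], na.rm = TRUE)
  else rep(0, nrow(v))
  data.frame(gene = rownames(v), mean = mu, sd = sdev,
             cv = sdev / mu, n = n, tech_cv = tech,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract one (sex, condition) block of log2 expression
#'
#' @return Gene-by-replica matrix of log2 values.
#' @keywords internal
.log2_block <- function(cohort, sex, condition) {
  ids <- .sample_ids(cohort, sex, condition)
  log2(cohort$values[, ids, drop = FALSE])
}
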