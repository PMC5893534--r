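#' Pearson correlation between two genes' replica profiles
#'
#' Product-moment correlation of the log2 expression levels of two
#' genes across the biological replicas of one condition.
#'
#' @param values_a,values_b Numeric vectors (>= 3 paired values);
#'   strictly positive when `log2_transform` is TRUE.
#' @param log2_transform Correlate log2 values (default TRUE); set
#'   FALSE when the inputs are already on the log scale.
#' @return Pearson r in \[-1, 1\]; `NA` when either vector is constant.
#' @export
pearson_r <- function(values_a, values_b, log2_transform = TRUE) {
  keep <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[keep]
  b <- values_b[keep]
  if (length(a) < 3)
    stop("need >= 3 paired values for a correlation")
  if (log2_transform) {
    if (any(a <= 0) || any(b <= 0))
      stop("values must be positive for the log2 scale")
    a <- log2(a)
    b <- log2(b)
  }
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Two-tailed p-value of a Pearson correlation
#'
#' From the exact t transform `t = r * sqrt((n-2) / (1-r^2))` on
#' `n - 2` degrees of freedom. `|r| = 1` gives p = 0 by convention.
#'
#' @param r Pearson correlation.
#' @param n Number of paired observations (>= 3).
#' @return Two-tailed p-value.
#' @export
correlation_p <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1, na.rm = TRUE))
  p <- rep(NA_real_, length(r))
  perfect <- !is.na(r) & abs(r) == 1
  p[perfect] <- 0
  ok <- !is.na(r) & abs(r) < 1
  t_stat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(t_stat), n - 2)
  p
}

#' Minimal |r| significant at level alpha for n replicas
#'
#' Inverts the t transform of [correlation_p()]; with n = 4 replicas
#' and alpha = 0.05 this is 0.950 (3 d.p.), so the per-pair
#' significance rule is equivalent to |r| >= 0.950 there.
#'
#' @param n Number of paired observations (>= 3).
#' @param alpha Two-tailed significance level.
#' @return Smallest |r| with p < alpha.
#' @export
r_threshold <- function(n, alpha = 0.05) {
  tc <- qt(1 - alpha / 2, n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Coordination network of a pathway within one condition
#'
#' Classifies every unordered pair of pathway genes by the Pearson
#' correlation of their log2 expression across the condition's
#' biological replicas: synergistic (r > 0, p < alpha), antagonistic
#' (r < 0, p < alpha) or independent. Expressions of genes whose
#' products work together in a pathway are expected to be coordinated;
#' the network makes that structure visible per condition. Genes with
#' constant replica profiles cannot be correlated and are skipped
#' (with a message).
#'
#' @param cohort An `ExpressionCohort`.
#' @param sex `"male"` or `"female"`.
#' @param condition Condition whose replicas are correlated.
#' @param genes Pathway gene ids (>= 2 quantified), or NULL for all
#'   genes (use with care: pairs grow quadratically).
#' @param alpha Per-pair significance level (default 0.05; no
#'   correction across pairs — the expected false-edge fraction under
#'   independence is alpha).
#' @return Data frame of all pairs: `gene_a`, `gene_b`, `r`, `p`,
#'   `class`; attribute `degree` holds the per-gene count of
#'   significant (synergistic + antagonistic) edges.
#' @export
build_network <- function(cohort, sex, condition, genes = NULL,
                          alpha = 0.05) {
  lv <- .log2_block(cohort, sex, condition)
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(lv))
    lv <- lv[genes, , drop = FALSE]
  }
  if (ncol(lv) < 3)
    stop("need >= 3 replicas to build a network")
  constant <- apply(lv, 1, function(z) sd(z, na.rm = TRUE) == 0)
  if (any(constant)) {
    message(sum(constant), " constant gene(s) skipped")
    lv <- lv[!constant, , drop = FALSE]
  }
  if (nrow(lv) < 2)
    stop("need >= 2 non-constant pathway genes")
  n <- ncol(lv)
  rmat <- cor(t(lv), use = "pairwise.complete.obs")
  pair <- which(upper.tri(rmat), arr.ind = TRUE)
  r <- rmat[pair]
  p <- correlation_p(r, n)
  class <- rep("independent", length(r))
  class[!is.na(p) & p < alpha & r > 0] <- "synergistic"
  class[!is.na(p) & p < alpha & r < 0] <- "antagonistic"
  edges <- data.frame(gene_a = rownames(lv)[pair[, 1]],
                      gene_b = rownames(lv)[pair[, 2]],
                      r = r, p = p, class = class,
                      stringsAsFactors = FALSE)
  sig <- edges$class != "independent"
  degree <- table(factor(c(edges$gene_a[sig], edges$gene_b[sig]),
                         levels = rownames(lv)))
  attr(edges, "degree") <- setNames(as.integer(degree), rownames(lv))
  edges
}
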