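#' Signed fold-change between two positive means
#'
#' The ratio convention used throughout: `mu_test / mu_ref` when the
#' test mean is at least the reference mean, and `-mu_ref / mu_test`
#' otherwise, so `|x| >= 1` always and the sign carries the direction
#' (negative for down-regulation). Equal means give +1.
#'
#' @param mu_test,mu_ref Positive linear-scale means (vectorized).
#' @return Signed fold-change x with `|x| >= 1`.
#' @export
signed_fold_change <- function(mu_test, mu_ref) {
  if (any(!is.finite(mu_test) | mu_test <= 0) ||
      any(!is.finite(mu_ref) | mu_ref <= 0))
    stop("means must be positive and finite")
  ifelse(mu_test >= mu_ref, mu_test / mu_ref, -mu_ref / mu_test)
}

#' Adaptive per-gene fold-change cut-off
#'
#' Replaces a fixed fold-change threshold (e.g. 1.5x for every gene)
#' with a gene-specific value derived from that gene's own measured
#' variability: the pooled (root-sum-square) contribution of the
#' biological CVs in the two compared conditions and the technical CVs
#' of the probing spots. A noisy gene must move further to be called;
#' a tight one is called on a smaller change.
#'
#' @param cv_test,cv_ref Biological coefficients of variation (sd/mean
#'   across replicas) in the test and reference conditions.
#' @param tech_cv_test,tech_cv_ref Technical CVs (across a gene's
#'   probes); default 0 when only gene-level data exist.
#' @return Cut-off `>= 1`: `1 + sqrt(cv_test^2 + cv_ref^2 +
#'   tech_cv_test^2 + tech_cv_ref^2)`.
#' @export
adaptive_cutoff <- function(cv_test, cv_ref,
                            tech_cv_test = 0, tech_cv_ref = 0) {
  cvs <- cbind(cv_test, cv_ref, tech_cv_test, tech_cv_ref)
  if (any(cvs < 0, na.rm = TRUE))
    stop("CVs must be non-negative")
  1 + sqrt(rowSums(cvs^2))
}

# Vectorized Welch (unequal-variance) two-sample p-value from summary
# statistics. Zero variance on both sides: p = 1 if the means agree,
# else 0 (a certain difference).
.welch_p_stats <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- !is.na(se2) & se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Heteroscedastic (Welch) t-test p-value for two replica sets
#'
#' Two-tailed two-sample unequal-variance t-test of the means'
#' equality with Welch-Satterthwaite degrees of freedom. Expression
#' ratios are multiplicative, so the test is performed on
#' log2-transformed values by default; the fold-change and WPR means
#' stay on the linear scale.
#'
#' @param replicas_test,replicas_ref Numeric vectors (>= 2 values
#'   each); strictly positive when `log2_transform` is TRUE.
#' @param log2_transform Test on log2 values (default TRUE).
#' @return Two-tailed p-value in (0, 1]; exactly 1 when both sides are
#'   constant and equal.
#' @export
welch_p <- function(replicas_test, replicas_ref, log2_transform = TRUE) {
  x <- replicas_test[!is.na(replicas_test)]
  y <- replicas_ref[!is.na(replicas_ref)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 values per side for the Welch test")
  if (log2_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop("values must be positive for the log2-scale test")
    x <- log2(x)
    y <- log2(y)
  }
  .welch_p_stats(mean(x), stats::var(x), length(x),
                 mean(y), stats::var(y), length(y))
}

#' Combined regulation call
#'
#' A gene is called up- (U) or down- (D) regulated only when both
#' criteria hold: its absolute fold-change reaches the gene's adaptive
#' cut-off AND the Welch p-value is below `alpha`; otherwise X (not
#' significantly regulated). A fold-change exactly at the cut-off
#' counts as regulated (>= / <= convention, mirroring the ">=" branch
#' of the signed fold-change).
#'
#' @param x Signed fold-change (`|x| >= 1`).
#' @param cut Adaptive cut-off (`>= 1`).
#' @param p Welch p-value.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of calls in {U, D, X}.
#' @export
call_regulation <- function(x, cut, p, alpha = 0.05) {
  stopifnot(all(abs(x) >= 1, na.rm = TRUE), all(cut >= 1, na.rm = TRUE))
  out <- rep("X", length(x))
  sig <- !is.na(p) & p < alpha
  out[sig & !is.na(x) & x >= cut] <- "U"
  out[sig & !is.na(x) & x <= -cut] <- "D"
  out
}

#' Per-gene regulation calls for one contrast
#'
#' Runs the full per-gene pipeline for a `condition` vs `ref` contrast
#' within one sex: condition means and CVs, signed fold-change,
#' adaptive cut-off (biological CVs of both conditions pooled with the
#' probe-level technical CVs when available), Welch p-value on log2
#' replicas, and the combined U/D/X call.
#'
#' @param cohort An `ExpressionCohort` (median-normalize first so the
#'   means are in array-median units).
#' @param sex `"male"` or `"female"`.
#' @param condition Test condition (e.g. `"BYS"`).
#' @param ref Reference condition (default `"BNS"`).
#' @param alpha Significance level for the call (default 0.05).
#' @return Data frame, one row per gene quantified in >= 2 replicas of
#'   both conditions: `gene`, `mu_ref`, `mu_test`, `cv_ref`,
#'   `cv_test`, `x`, `cut`, `p`, `call`.
#' @export
contrast_calls <- function(cohort, sex, condition,
                           ref = REFERENCE_CONDITION, alpha = 0.05) {
  st_test <- condition_stats(cohort, sex, condition)
  st_ref <- condition_stats(cohort, sex, ref)
  stopifnot(identical(st_test$gene, st_ref$gene))

  lt <- .log2_block(cohort, sex, condition)
  lr <- .log2_block(cohort, sex, ref)
  vt <- apply(lt, 1, stats::var, na.rm = TRUE)
  vr <- apply(lr, 1, stats::var, na.rm = TRUE)
  p <- .welch_p_stats(rowMeans(lt, na.rm = TRUE), vt, st_test$n,
                      rowMeans(lr, na.rm = TRUE), vr, st_ref$n)

  ok <- st_test$n >= 2 & st_ref$n >= 2 &
    is.finite(st_test$mean) & is.finite(st_ref$mean)
  x <- signed_fold_change(st_test$mean[ok], st_ref$mean[ok])
  cut <- adaptive_cutoff(st_test$cv[ok], st_ref$cv[ok],
                         st_test$tech_cv[ok], st_ref$tech_cv[ok])
  p <- p[ok]
  data.frame(gene = st_test$gene[ok],
             mu_ref = st_ref$mean[ok], mu_test = st_test$mean[ok],
             cv_ref = st_ref$cv[ok], cv_test = st_test$cv[ok],
             x = x, cut = cut, p = p,
             call = call_regulation(x, cut, p, alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transition class of a gene across disease and treated contrasts
#'
#' Combines a gene's call in the disease-vs-reference comparison with
#' its call in the treated-vs-reference comparison into one of the
#' nine two-letter classes (e.g. `DX` = down-regulated in disease,
#' restored under treatment; `XU` = untouched by disease, up-regulated
#' by the treatment — a side effect).
#'
#' @param call_disease,call_treated Calls in {U, D, X} (vectorized).
#' @return Two-letter class string(s).
#' @export
classify_transition <- function(call_disease, call_treated) {
  if (!all(call_disease %in% CALL_LEVELS) ||
      !all(call_treated %in% CALL_LEVELS))
    stop("calls must be in {U, D, X}")
  paste0(call_disease, call_treated)
}

#' Count the nine transition classes over genes shared by two contrasts
#'
#' @param calls_disease,calls_treated Data frames from
#'   [contrast_calls()] for the disease and treated contrasts (both vs
#'   the same reference). Genes are matched by id; genes present in
#'   only one contrast are excluded.
#' @return Named integer vector over all nine classes (class
#'   `TransitionTable`); its sum equals the number of genes contrasted
#'   in both comparisons.
#' @export
transition_table <- function(calls_disease, calls_treated) {
  common <- intersect(calls_disease$gene, calls_treated$gene)
  cd <- calls_disease$call[match(common, calls_disease$gene)]
  ct <- calls_treated$call[match(common, calls_treated$gene)]
  cls <- factor(classify_transition(cd, ct), levels = TRANSITION_CLASSES)
  structure(setNames(as.integer(table(cls)), TRANSITION_CLASSES),
            class = "TransitionTable")
}
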