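#' Read pathway gene sets from a GMT file
#'
#' One pathway per line: id, description, then gene ids (tab-separated).
#' Parsing is delegated to [fgsea::gmtPathways()].
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  pathways <- fgsea::gmtPathways(path)
  if (!length(pathways)) stop("no pathways in ", path)
  pathways
}

#' Percentages of up- and down-regulated genes in a pathway
#'
#' The denominator is the number of the pathway's genes actually
#' quantified in the contrast (not the nominal pathway size).
#'
#' @param calls Data frame from [contrast_calls()].
#' @param genes Character vector of pathway gene ids, or NULL for the
#'   whole transcriptome.
#' @return Named numeric `c(pct_up, pct_down)` in percent.
#' @export
pathway_percentages <- function(calls, genes = NULL) {
  sub <- if (is.null(genes)) calls else calls[calls$gene %in% genes, ]
  if (!nrow(sub))
    stop("no pathway gene quantified in this contrast")
  c(pct_up = 100 * mean(sub$call == "U"),
    pct_down = 100 * mean(sub$call == "D"))
}

#' Weighted Pathway Regulation (WPR)
#'
#' Cut-off-free measure of how much a condition alters a pathway's
#' transcriptome: the average, over ALL quantified pathway genes (no
#' significance filter), of
#' \deqn{\mu_i^{(ref)} \, (|x_i| - 1) \, (1 - p_i)}
#' i.e. each gene contributes proportionally to its normal expression
#' level (in array-median units after [normalize_median()]), its net
#' fold-change, and the confidence of its regulation. Unregulated
#' genes (|x| = 1 or p = 1) contribute 0, so WPR >= 0, and WPR scales
#' linearly with the expression units — hence the median-units
#' normalization.
#'
#' @param contrasts Data frame from [contrast_calls()] (needs columns
#'   `gene`, `mu_ref`, `x`, `p`).
#' @param genes Pathway gene ids, or NULL for the whole transcriptome.
#' @return Non-negative scalar.
#' @export
wpr <- function(contrasts, genes = NULL) {
  sub <- if (is.null(genes)) contrasts
         else contrasts[contrasts$gene %in% genes, ]
  if (!nrow(sub))
    stop("no pathway gene quantified in this contrast")
  mean(sub$mu_ref * (abs(sub$x) - 1) * (1 - sub$p))
}

#' Gene Expression Recovery (GER)
#'
#' Percentage balance of genes the treatment restored against genes it
#' newly dysregulated:
#' \deqn{GER = \frac{\{DX\}+\{UX\}-\{XD\}-\{XU\}}
#'   {\{DX\}+\{UX\}+\{XD\}+\{XU\}+\{DD\}+\{DU\}+\{UD\}+\{UU\}} \times 100}
#' Genes regulated in neither comparison ({XX}) do not enter. +100
#' means every disease-regulated gene was restored with no side
#' effects; -100 means pure side effects.
#'
#' @param transitions A `TransitionTable` from [transition_table()],
#'   or any named vector covering the nine classes.
#' @return Percentage in \[-100, 100\]; `NA` (with a warning) when no
#'   gene was regulated in either comparison — not applicable, never 0.
#' @export
ger <- function(transitions) {
  tt <- transitions[TRANSITION_CLASSES]
  if (anyNA(tt)) stop("transition table must cover all nine classes")
  num <- tt[["DX"]] + tt[["UX"]] - tt[["XD"]] - tt[["XU"]]
  den <- sum(tt) - tt[["XX"]]
  if (den == 0) {
    warning("all genes are XX: GER not applicable")
    return(NA_real_)
  }
  100 * num / den
}

#' Pathway Restoration Efficiency (PRE)
#'
#' Percent reduction of a pathway's WPR under treatment relative to
#' the untreated disease condition:
#' \deqn{PRE = (1 - WPR_{treated} / WPR_{untreated}) \times 100}
#' Outcomes: 100 = full recovery (treated WPR 0); in (0, 100) =
#' positive effect; 0 = null effect; negative = the treatment made the
#' pathway more altered.
#'
#' @param wpr_treated WPR of the treated condition (e.g. BYA vs BNS).
#' @param wpr_untreated WPR of the untreated disease condition (BYS vs
#'   BNS); must be > 0 for the ratio to be defined.
#' @return Percentage `<= 100`; `NA` (with a warning) when
#'   `wpr_untreated` is 0.
#' @export
pre <- function(wpr_treated, wpr_untreated) {
  if (any(wpr_treated < 0, na.rm = TRUE) ||
      any(wpr_untreated < 0, na.rm = TRUE))
    stop("WPR values must be non-negative")
  out <- 100 * (1 - wpr_treated / wpr_untreated)
  zero <- !is.na(wpr_untreated) & wpr_untreated == 0
  if (any(zero)) {
    warning("untreated WPR is 0: PRE not applicable")
    out[zero] <- NA_real_
  }
  out
}

#' Compare two treatments across pathway-level scores
#'
#' Two-tailed heteroscedastic (Welch) t-test over the per-pathway
#' scores (e.g. the five synapse PRE values) of treatment A vs
#' treatment B. Unpaired by default; set `paired = TRUE` to pair
#' pathways.
#'
#' @param scores_a,scores_b Numeric vectors of per-pathway scores
#'   (>= 2 values each).
#' @param paired Pair the pathways instead of the unpaired test.
#' @return Two-tailed p-value.
#' @export
compare_treatments <- function(scores_a, scores_b, paired = FALSE) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("need >= 2 pathway scores per treatment")
  if (stats::var(scores_a) == 0 && stats::var(scores_b) == 0 &&
      ((paired && all(scores_a == scores_b)) ||
       (!paired && mean(scores_a) == mean(scores_b))))
    return(1)
  t.test(scores_a, scores_b, paired = paired, var.equal = FALSE)$p.value
}

#' Power of a fixed-effects one-way ANOVA
#'
#' @param n Per-group sample size.
#' @param f Cohen's effect size f (between-group sd / within-group sd).
#' @param k Number of groups.
#' @param alpha Significance level.
#' @return Power: the upper tail of the noncentral F distribution
#'   (noncentrality `f^2 * k * n`, df `k-1` and `k*n-k`) above the
#'   central-F critical value at `alpha`.
#' @export
anova_power <- function(n, f, k, alpha = 0.05) {
  stopifnot(f > 0, k >= 2, alpha > 0, alpha < 1, all(n >= 2))
  df1 <- k - 1
  df2 <- k * n - k
  1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = f^2 * k * n)
}

#' Smallest per-group sample size reaching a target ANOVA power
#'
#' Searches the smallest integer `n >= 2` whose fixed-effects one-way
#' ANOVA power (see [anova_power()]) reaches `power`.
#'
#' @param f Cohen's effect size f.
#' @param k Number of groups.
#' @param alpha Significance level.
#' @param power Target power.
#' @param n_max Search bound; exceeding it is an explicit failure
#'   (unreachable power, e.g. f near 0).
#' @return Integer per-group sample size.
#' @export
anova_sample_size <- function(f, k, alpha = 0.05, power = 0.80,
                              n_max = 100000L) {
  stopifnot(f > 0, k >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max)
    if (anova_power(n, f, k, alpha) >= power) return(n)
  stop("target power ", power, " not reached by n = ", n_max)
}

#' Full pathway score table for one sex
#'
#' Runs every treatment-relevant contrast (BYS, BYA, BYP vs BNS) for
#' one sex and scores each pathway (plus `ALL`, the whole transcriptome
#' treated as one large pathway): percent up/down, WPR for every
#' condition, and GER/PRE for the two treatments. Genes shared by
#' several pathways contribute fully to each.
#'
#' @param cohort A median-normalized `ExpressionCohort`.
#' @param sex `"male"` or `"female"`.
#' @param pathways Named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param alpha Significance level for the regulation calls.
#' @param conditions Test conditions to contrast vs BNS; defaults to
#'   those of BYS/BYA/BYP present in the cohort.
#' @return List with `scores` (data frame: sex, pathway, condition,
#'   n_genes, pct_up, pct_down, wpr, ger, pre) and `calls` (the
#'   per-contrast call tables, named by condition).
#' @export
score_pathways <- function(cohort, sex, pathways, alpha = 0.05,
                           conditions = NULL) {
  present <- unique(cohort$samples$condition[cohort$samples$sex == sex])
  if (is.null(conditions))
    conditions <- intersect(c(DISEASE_CONDITION, TREATMENTS), present)
  calls <- lapply(setNames(conditions, conditions), function(cond)
    contrast_calls(cohort, sex, cond, alpha = alpha))

  sets <- c(list(ALL = NULL), pathways)
  rows <- list()
  for (cond in conditions) {
    for (pw in names(sets)) {
      genes <- sets[[pw]]
      pct <- pathway_percentages(calls[[cond]], genes)
      w <- wpr(calls[[cond]], genes)
      g_val <- NA_real_
      p_val <- NA_real_
      if (cond %in% TREATMENTS && DISEASE_CONDITION %in% conditions) {
        cd <- calls[[DISEASE_CONDITION]]
        ct <- calls[[cond]]
        if (!is.null(genes)) {
          cd <- cd[cd$gene %in% genes, ]
          ct <- ct[ct$gene %in% genes, ]
        }
        tt <- transition_table(cd, ct)
        g_val <- if (sum(tt) - tt[["XX"]] > 0) ger(tt) else NA_real_
        w_dis <- wpr(calls[[DISEASE_CONDITION]], genes)
        p_val <- if (w_dis > 0) pre(w, w_dis) else NA_real_
      }
      n_genes <- if (is.null(genes)) nrow(calls[[cond]])
                 else sum(calls[[cond]]$gene %in% genes)
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sex, pathway = pw, condition = cond, n_genes = n_genes,
        pct_up = pct[["pct_up"]], pct_down = pct[["pct_down"]],
        wpr = w, ger = g_val, pre = p_val,
        stringsAsFactors = FALSE)
    }
  }
  list(scores = do.call(rbind, rows), calls = calls)
}
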