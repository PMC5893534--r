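#' Published pathway WPR scores
#'
#' The published pathway-level WPR values for the disease (BYS vs BNS)
#' contrast of the motivating rat infantile-spasms arcuate-nucleus
#' study: the whole transcriptome (`ALL`), the GABAergic synapse
#' (`GABA`) and the five-synapse average (`NEUROTRANSMISSION`), for
#' each sex. Shipped as a plain-text fixture so score *ratios* (e.g.
#' the male/female alteration ratio) can be recomputed without the
#' underlying array data. Absolute WPR magnitudes depend on the
#' expression normalization used when they were computed and are not
#' comparable to WPRs computed by this package on other data; only
#' ratios within the table are meaningful.
#'
#' @return Data frame with columns `pathway`, `sex`, `wpr`.
#' @export
published_wpr_scores <- function() {
  read.delim(system.file("extdata", "published_wpr_scores.tsv",
                         package = "pathfabric", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Male/female WPR alteration ratio for one pathway
#'
#' @param scores Data frame as returned by [published_wpr_scores()]
#'   (or any table with `pathway`, `sex`, `wpr`).
#' @param pathway Pathway label, e.g. `"ALL"` or `"GABA"`.
#' @return The male WPR divided by the female WPR.
#' @export
wpr_sex_ratio <- function(scores, pathway) {
  m <- scores$wpr[scores$pathway == pathway & scores$sex == "male"]
  f <- scores$wpr[scores$pathway == pathway & scores$sex == "female"]
  if (length(m) != 1 || length(f) != 1)
    stop("need exactly one male and one female WPR for ", pathway)
  m / f
}
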