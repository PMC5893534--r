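---
title: "Quantifying pathway alteration and treatment recovery with WPR, GER and PRE"
author: "pathfabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pathway alteration and treatment recovery with WPR, GER and PRE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathfabric)
```

## The problem

Small replicated expression studies — the motivating design is an
infantile-spasms rat model profiled on two-colour 4×44k microarrays,
with 2 sexes × 5 conditions × 4 biological replicas of the hypothalamic
arcuate nucleus — ask two questions that per-gene lists answer poorly:

1. *How strongly does a disease condition alter the transcriptome of a
   functional pathway?* Counting "significantly regulated" genes hides
   everything below an arbitrary fold-change cut-off and weights a
   barely-significant gene the same as a massively regulated hub.
2. *How completely does a treatment restore it?* A reduced count of
   regulated genes ignores genes the treatment itself dysregulates.

pathfabric implements a coherent scoring stack for both questions,
plus a synthetic-cohort generator with a planted ground truth so the
whole stack can be validated end to end without array data.

Condition codes are three letters: prenatal Betamethasone/Saline,
spasms Yes/No, postnatal treatment ACTH/PMX53/Saline. `BNS`
(betamethasone-primed, no spasms, saline) is the reference for every
contrast; `BYS` is the untreated disease condition; `BYA` and `BYP`
are the two treatments.

## Per-gene regulation calls

For gene $i$ in contrast $\alpha$ vs BNS, with linear-scale condition
means $\mu_i^{(\alpha)}, \mu_i^{(BNS)}$ over the replicas:

$$x_i = \begin{cases}
  \mu_i^{(\alpha)}/\mu_i^{(BNS)} & \mu_i^{(\alpha)} \ge \mu_i^{(BNS)}\\
  -\mu_i^{(BNS)}/\mu_i^{(\alpha)} & \text{otherwise}
\end{cases}$$

so $|x_i| \ge 1$ and the sign carries the direction. A gene is called
U (up) or D (down) only when **both** criteria hold:

* $|x_i| \ge \mathrm{cut}_i = 1 + \sqrt{cv_{test}^2 + cv_{ref}^2 +
  tcv_{test}^2 + tcv_{ref}^2}$, the pooled (root-sum-square)
  contribution of the gene's biological CVs in the two conditions and
  the technical CVs across its probes — an *adaptive* cut-off: noisy
  genes must move further;
* the two-tailed heteroscedastic (Welch) $t$-test of the means'
  equality gives $p_i < \alpha$ (default 0.05; the joint criterion
  deliberately uses a raw, uncorrected $\alpha$, with `alpha` exposed
  for users who want otherwise).

Everything else is X. Transition classes pair the disease call with
the treated call: `DX` = down in disease, restored under treatment;
`XU` = newly up-regulated by the treatment (a side effect); nine
classes in all.

## Pathway scores

**WPR (Weighted Pathway Regulation)** of pathway $\Gamma$ under
condition $\alpha$:

$$WPR_\Gamma^{(\alpha)} = \left\langle \mu_i^{(BNS)}\,(|x_i| - 1)\,(1 - p_i)
\right\rangle_{i \in \Gamma}$$

The average runs over **all** quantified pathway genes — $(1-p_i)$ is
a confidence *weight*, not a filter — so WPR is cut-off-free: every
gene contributes in proportion to its normal expression level, its net
fold-change and the confidence of its regulation. WPR $\ge 0$, and
WPR $= 0$ exactly when every gene has $|x| = 1$ or $p = 1$.

**GER (Gene Expression Recovery)**, from the transition counts:

$$GER = \frac{\{DX\}+\{UX\}-\{XD\}-\{XU\}}
  {\{DX\}+\{UX\}+\{XD\}+\{XU\}+\{DD\}+\{DU\}+\{UD\}+\{UU\}} \times 100\,\%$$

the balance of restored genes against treatment side effects, over all
genes regulated in either comparison ({XX} genes do not enter; an
all-XX table is *not applicable*, never 0).

**PRE (Pathway Restoration Efficiency)**:

$$PRE_\Gamma = \left(1 - WPR_\Gamma^{(treated)}/WPR_\Gamma^{(BYS)}\right)
\times 100\,\%$$

with the four outcome classes: 100 = full recovery, (0, 100) =
positive effect, 0 = null effect, negative = the treatment made the
pathway worse. PRE inherits WPR's cut-off-freedom, which is why it can
disagree with GER when many genes sit near the significance boundary.

**Coordination networks.** Within one (sex, condition), gene pairs are
classified from the Pearson correlation of their log2 expression
across the four replicas: synergistic ($r > 0$, $p < 0.05$),
antagonistic ($r < 0$, $p < 0.05$), independent otherwise. With $n=4$
this is exactly $|r| \ge 0.950$ (3 d.p.). No across-pair correction is
applied (per-pair $\alpha$, as in the source design); the expected
false-edge fraction under independence is therefore $\alpha$, and the
suite verifies that calibration so users can interpret edge counts.

**ANOVA power.** `anova_power()`/`anova_sample_size()` implement
fixed-effects one-way ANOVA power from the noncentral $F$ distribution
($\lambda = f^2 k n$, df $k-1$ and $kn-k$). The motivating worked
example — Cohen's $f = 0.7972$, $k = 3$, $\alpha = 0.05$, power 0.80 —
gives $n = 7$ per group.

## Numerical and design choices

* **Units for $\mu$.** WPR is linear in $\mu^{(BNS)}$, so raw
  fluorescence units would make it arbitrary. `normalize_median()`
  divides each array by its own median; all means are then in
  dimensionless array-median units and WPR is $O(0.1\!-\!10)$.
  Consequence: WPR values are only comparable *within* one
  normalization scheme — cross-study WPR magnitudes are not
  meaningful, ratios under one scheme are.
* **Test scale.** The Welch test runs on log2 values (ratios are
  multiplicative); $x$ and $\mu$ stay linear. Both variances zero with
  equal means gives $p = 1$; fewer than 2 replicas per side is refused
  rather than guessed.
* **Boundary conventions.** $x$ at equal means is $+1$ (the $\ge$
  branch); $|x|$ exactly at the cut-off counts as regulated; $|r| = 1$
  gives $p = 0$ by convention and constant replica profiles are
  skipped with a message.
* **Probe summarization.** Gene value = median of its probes per
  sample (robust to single bad spots); the probe spread is kept as a
  technical CV and enters the cut-off rather than the point estimate.
* **Missing values.** Per-gene statistics are computed on available
  replicas with the reduced $n$ recorded; genes quantified in one sex
  only are analyzed within that sex (the two sexes are processed as
  independent cohorts end to end; only score ratios cross sexes).
* **Treatment comparison.** `compare_treatments()` is an *unpaired*
  Welch test across the five synapse-pathway scores by default —
  nothing in the design forces a pairing of pathways — with
  `paired = TRUE` exposed.

## What the generator emulates — and what it does not

`generate_cohort()` draws per-gene lognormal baselines
(`2^N(6, 1.5)`, a typical 4×44k intensity spread), per-gene biological
CVs uniform in 0.05–0.40, multiplicative planted effects on 30% of
genes in BYS (|FC| uniform in 1.5–4, half up), treatment conditions
that copy the BYS effects and then revert a recovery fraction
$\rho$ (defaults BYA 0.65 < BYP 0.75, mirroring the reported ordering
of the two treatments) while newly perturbing a side-effect fraction
$\sigma = 0.05$ of unaffected genes, lognormal replicate noise at the
gene's CV, 1–4 probes per gene with 5% technical CV, ~3.5% of genes
unquantified in females, and female effect sizes scaled to 1/3 on the
$|FC|-1$ scale (so regulated *percentages* stay similar while the WPR
ratio separates the sexes — the property the score exists to capture).
SNS is generated identically to BNS; the SNS↔BNS priming contrast is
out of analytic scope. Where no measured estimate exists (effect-size
distribution, technical noise magnitude), these defaults are one-time
choices of plausible microarray magnitudes, not estimates of any real
dataset.

Not emulated: dye/channel structure of two-colour arrays, spatial
artifacts, correlated gene–gene noise (coordination beyond planted
mean effects), probe-specific biases, batch effects. Passing tests
therefore demonstrate the *scoring machinery* is correct and
calibrated under the stated noise model — not that real arrays meet
that model.

## Known limitations

* The called *percentage* of regulated genes is biased upward by
  $\alpha(1-\pi)$ under the raw-$\alpha$ joint criterion ($\pi$ = true
  regulated fraction): at $\alpha = 0.05$ and $\pi = 0.3$ that is ~3.5
  points when sensitivity is near 1, and the adaptive cut-off cannot
  remove it (the smallest log-ratio reaching $p < 0.05$ at $n = 4$,
  $\approx 1.73\,cv$, exceeds the cut-off offset $\approx 1.41\,cv$).
  This is an inherent property of the uncorrected joint criterion;
  WPR/GER/PRE-level conclusions are much less sensitive to it than
  the raw percentages.
* With 4 replicas, edge significance needs $|r| \ge 0.950$; networks
  are sparse and individual edges unstable — degree summaries and
  within/between-set densities are the interpretable outputs.
* Absolute WPR magnitudes depend on the normalization; only ratios
  within one scheme should be compared.
* Between-group WPR ratios are diluted toward 1 by the null-background
  term (the noise contribution of unregulated genes, common to both
  groups). With female effects planted at 1/3 of male $|FC|-1$, the
  planted-effect-only ratio would be near 3, but the realized
  whole-transcriptome ratio on default cohorts averages ~2.5. Ratios
  of pathway WPRs understate planted effect-size ratios whenever the
  background share of WPR is non-negligible.

## Problem sizes in the shipped suite

The test suite validates calibration and parameter recovery on cohorts
of 50–2,000 genes across 4–20 seeds, and the monotonicity of GER/PRE
in the planted recovery fraction on 20 seeds of 250–300 genes — sizes
at which the binomial/sampling error of the checked quantities is well
below the asserted tolerances. The generator's defaults (17,000 genes)
are what an analysis-scale simulation should use.

## A minimal run

```{r example, eval = FALSE}
cfg <- cohort_config(n_genes = 2000, seed = 1)
sim <- generate_cohort(cfg)
cohort <- normalize_median(sim$cohort)

res <- score_pathways(cohort, "male", sim$truth$pathways)
head(res$scores)

edges <- build_network(cohort, "male", "BYS", sim$truth$pathways$GABA)
table(edges$class)

anova_sample_size(f = 0.7972, k = 3, alpha = 0.05, power = 0.80)  # 7
```
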