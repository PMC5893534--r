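#' Configuration for a synthetic expression cohort
#'
#' Defaults emulate the study design the package targets: two sexes,
#' five conditions (SNS, BNS, BYS, BYA, BYP) with four biological
#' replicas each, ~17,000 genes (a few percent quantified in males
#' only), multi-probe genes, lognormal expression, ~30% of genes
#' regulated in the disease condition (BYS) vs the reference (BNS),
#' and partial recovery with side effects under the two treatments
#' (BYA, BYP). The female cohort carries the same planted gene sets
#' but effect sizes scaled by `sex_effect_scale` on the |FC|-1 scale,
#' so regulated percentages stay similar while the WPR alteration
#' score separates the sexes.
#'
#' @param n_genes Number of genes.
#' @param n_pathways Number of planted pathways (5 gives the synapse
#'   labels GLU/ACH/5HT/GABA/DA).
#' @param pathway_size Range `c(min, max)` of pathway sizes; pathways
#'   are drawn independently, so genes may belong to several.
#' @param n_replicas Biological replicas per (sex, condition); >= 2.
#' @param conditions Ordered condition set; must contain BNS.
#' @param baseline_log2_mean,baseline_log2_sd Lognormal baseline: per
#'   gene mean expression is `2^N(mean, sd)`.
#' @param biological_cv Range of per-gene biological CVs (fraction).
#' @param technical_cv Probe-level technical CV (fraction).
#' @param probes_per_gene Range of probes per gene; 0 or `c(1, 1)`
#'   disables the probe table.
#' @param frac_regulated Fraction of genes regulated in BYS vs BNS.
#' @param effect_fc_range Range of planted |fold-changes|; lower
#'   bound > 1.
#' @param frac_up Fraction of planted effects that are up-regulations.
#' @param recovery_frac Named fractions `c(BYA = , BYP = )` of planted
#'   BYS effects reverted to baseline under each treatment.
#' @param side_effect_frac Named fractions `c(BYA = , BYP = )` of
#'   unaffected genes newly regulated by each treatment.
#' @param sex_effect_scale Multiplier on |FC - 1| for the female
#'   cohort (default 1/3).
#' @param frac_female_missing Fraction of genes not quantified in the
#'   female cohort (NA there), mimicking per-sex quantified-gene
#'   counts.
#' @param sexes Sexes to generate.
#' @param seed Integer seed; the cohort and its truth are reproducible
#'   from (config, seed).
#' @return A validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_genes = 17000L, n_pathways = 5L,
                          pathway_size = c(40L, 90L), n_replicas = 4L,
                          conditions = CONDITIONS,
                          baseline_log2_mean = 6, baseline_log2_sd = 1.5,
                          biological_cv = c(0.05, 0.40),
                          technical_cv = 0.05,
                          probes_per_gene = c(1L, 4L),
                          frac_regulated = 0.30,
                          effect_fc_range = c(1.5, 4.0),
                          frac_up = 0.5,
                          recovery_frac = c(BYA = 0.65, BYP = 0.75),
                          side_effect_frac = c(BYA = 0.05, BYP = 0.05),
                          sex_effect_scale = 1 / 3,
                          frac_female_missing = 0.035,
                          sexes = c("male", "female"),
                          seed = 1L) {
  cfg <- list(n_genes = n_genes, n_pathways = n_pathways,
              pathway_size = pathway_size, n_replicas = n_replicas,
              conditions = conditions,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              biological_cv = biological_cv, technical_cv = technical_cv,
              probes_per_gene = probes_per_gene,
              frac_regulated = frac_regulated,
              effect_fc_range = effect_fc_range, frac_up = frac_up,
              recovery_frac = recovery_frac,
              side_effect_frac = side_effect_frac,
              sex_effect_scale = sex_effect_scale,
              frac_female_missing = frac_female_missing,
              sexes = sexes, seed = seed)
  counts <- c(n_genes = n_genes, n_pathways = n_pathways,
              n_replicas = n_replicas, pathway_size, probes_per_gene)
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  if (n_replicas < 2) stop("n_replicas must be >= 2")
  fracs <- c(frac_regulated, frac_up, recovery_frac, side_effect_frac,
             frac_female_missing, sex_effect_scale)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (!length(conditions)) stop("empty condition set")
  if (!all(conditions %in% CONDITIONS))
    stop("unknown condition(s): ",
         paste(setdiff(conditions, CONDITIONS), collapse = ", "))
  if (!REFERENCE_CONDITION %in% conditions)
    stop("conditions must include the reference ", REFERENCE_CONDITION)
  if (effect_fc_range[1] <= 1)
    stop("effect_fc_range lower bound must exceed 1")
  if (any(biological_cv < 0) || technical_cv < 0)
    stop("CVs must be non-negative")
  if (pathway_size[2] > n_genes)
    stop("pathway_size exceeds n_genes")
  if (!all(c("BYA", "BYP") %in% names(recovery_frac)) ||
      !all(c("BYA", "BYP") %in% names(side_effect_frac)))
    stop("recovery_frac and side_effect_frac need BYA and BYP entries")
  structure(cfg, class = "CohortConfig")
}

# sample() that never expands a length-1 numeric into 1:n.
.sample_range <- function(values, n) {
  if (length(values) == 1L) rep(values, n)
  else sample(values, n, replace = TRUE)
}

# Lognormal multiplicative noise with unit linear-scale mean and the
# requested coefficient of variation.
.lnorm_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n) * sdlog - sdlog^2 / 2)
}

# Linear multiplier from a signed fold-change (+1 -> 1, +2 -> 2,
# -2 -> 0.5).
.fc_to_multiplier <- function(fc) ifelse(fc >= 0, fc, -1 / fc)

# Scale a signed fold-change on the |FC|-1 scale (sex effect).
.scale_fc <- function(fc, s) sign(fc) * (1 + s * (abs(fc) - 1))

#' Generate a synthetic expression cohort with planted ground truth
#'
#' Draws per-gene lognormal baselines and biological CVs, plants
#' multiplicative regulation of `frac_regulated` of the genes in BYS
#' vs BNS, copies those effects into the treated conditions and then
#' reverts a `recovery_frac` of them to baseline while newly
#' perturbing a `side_effect_frac` of the unaffected genes
#' (treatment side effects), and finally adds per-replica lognormal
#' biological noise and, when a probe table is requested, per-probe
#' lognormal technical noise (the returned gene-level values are then
#' probe medians via [summarize_probes()]). SNS is generated
#' identically to BNS. Every gene is, per treatment, in exactly one of
#' {restored, persistent, side_effect, untouched}.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (an [expression_cohort()]) and `truth`
#'   (class `GroundTruth`: `$table` — one row per gene and non-BNS
#'   condition with signed true fold-changes `fc_male`/`fc_female`
#'   and the gene's status; `$pathways` — the planted gene sets;
#'   `$regulated`, `$treatments`, `$baseline`, `$bio_cv`, `$config`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  baseline <- setNames(2^rnorm(n, config$baseline_log2_mean,
                               config$baseline_log2_sd), genes)
  bio_cv <- setNames(runif(n, config$biological_cv[1],
                           config$biological_cv[2]), genes)

  sizes <- .sample_range(seq(config$pathway_size[1], config$pathway_size[2]),
                         config$n_pathways)
  pnames <- if (config$n_pathways == 5L) c("GLU", "ACH", "5HT", "GABA", "DA")
            else sprintf("P%02d", seq_len(config$n_pathways))
  pathways <- setNames(lapply(sizes, function(k) sample(genes, k)), pnames)

  n_reg <- round(config$frac_regulated * n)
  regulated <- sample(genes, n_reg)
  eff_sign <- ifelse(runif(n_reg) < config$frac_up, 1, -1)
  eff_fc <- setNames(eff_sign * runif(n_reg, config$effect_fc_range[1],
                                      config$effect_fc_range[2]),
                     regulated)
  unaffected <- setdiff(genes, regulated)

  # Signed true fold-change per gene for each non-reference condition
  # (male scale); SNS == BNS by design.
  fc_cond <- list(SNS = setNames(rep(1, n), genes),
                  BYS = setNames(rep(1, n), genes))
  fc_cond$BYS[regulated] <- eff_fc
  status <- list(SNS = setNames(rep("untouched", n), genes),
                 BYS = setNames(rep("untouched", n), genes))
  status$BYS[regulated] <- "regulated"
  treatments <- list()
  for (tr in TREATMENTS) {
    restored <- sample(regulated, round(config$recovery_frac[[tr]] * n_reg))
    persistent <- setdiff(regulated, restored)
    side <- sample(unaffected,
                   round(config$side_effect_frac[[tr]] * length(unaffected)))
    side_sign <- ifelse(runif(length(side)) < config$frac_up, 1, -1)
    side_fc <- setNames(side_sign * runif(length(side),
                                          config$effect_fc_range[1],
                                          config$effect_fc_range[2]), side)
    fc <- setNames(rep(1, n), genes)
    fc[persistent] <- eff_fc[persistent]
    fc[side] <- side_fc
    fc_cond[[tr]] <- fc
    st <- setNames(rep("untouched", n), genes)
    st[restored] <- "restored"
    st[persistent] <- "persistent"
    st[side] <- "side_effect"
    status[[tr]] <- st
    treatments[[tr]] <- list(restored = restored, persistent = persistent,
                             side_effect = side)
  }

  female_missing <- sample(genes, round(config$frac_female_missing * n))

  cond_use <- intersect(CONDITIONS, config$conditions)
  n_rep <- config$n_replicas
  use_probes <- config$probes_per_gene[2] > 1
  value_cols <- list()
  probe_cols <- list()
  sheet <- list()
  if (use_probes) {
    n_probes <- .sample_range(seq(config$probes_per_gene[1],
                                  config$probes_per_gene[2]), n)
    probe_gene <- rep(genes, n_probes)
    probe_id <- paste0(probe_gene, "_p",
                       unlist(lapply(n_probes, seq_len)))
  }

  for (sex in config$sexes) {
    s <- if (sex == "female") config$sex_effect_scale else 1
    for (cond in cond_use) {
      fc <- if (cond == REFERENCE_CONDITION) setNames(rep(1, n), genes)
            else .scale_fc(fc_cond[[cond]], s)
      mu <- baseline * .fc_to_multiplier(fc)
      for (r in seq_len(n_rep)) {
        id <- sprintf("%s_%s_%d", substr(sex, 1, 1), cond, r)
        signal <- mu * .lnorm_noise(n, bio_cv)
        if (sex == "female") signal[female_missing] <- NA_real_
        value_cols[[id]] <- signal
        if (use_probes)
          probe_cols[[id]] <- signal[probe_gene] *
            .lnorm_noise(length(probe_gene), config$technical_cv)
        sheet[[id]] <- data.frame(sample_id = id, sex = sex,
                                  condition = cond, replica = r,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, sheet)
  rownames(samples) <- NULL

  if (use_probes) {
    probe_values <- do.call(cbind, probe_cols)
    rownames(probe_values) <- probe_id
    probe_map <- data.frame(probe_id = probe_id, gene_id = probe_gene,
                            stringsAsFactors = FALSE)
    summ <- summarize_probes(probe_values, probe_map)
    values <- summ$values[genes, , drop = FALSE]
    tech_cv <- summ$tech_cv[genes, , drop = FALSE]
    cohort <- expression_cohort(values, samples,
                                probe_values = probe_values,
                                probe_map = probe_map, tech_cv = tech_cv)
  } else {
    values <- do.call(cbind, value_cols)
    rownames(values) <- genes
    cohort <- expression_cohort(values, samples)
  }

  truth_conditions <- setdiff(cond_use, REFERENCE_CONDITION)
  fc_female <- lapply(fc_cond, .scale_fc, s = config$sex_effect_scale)
  table <- do.call(rbind, lapply(truth_conditions, function(cond)
    data.frame(gene = genes, condition = cond,
               fc_male = unname(fc_cond[[cond]]),
               fc_female = unname(fc_female[[cond]]),
               status = unname(status[[cond]]),
               stringsAsFactors = FALSE)))
  truth <- structure(
    list(table = table, pathways = pathways, regulated = regulated,
         treatments = treatments, baseline = baseline, bio_cv = bio_cv,
         female_missing = female_missing, config = config),
    class = "GroundTruth")
  list(cohort = cohort, truth = truth)
}

#' Write / read the ground-truth ledger
#'
#' The ledger is a tab-delimited table keyed by gene and condition
#' (one row per gene per non-reference condition) with the signed true
#' fold-changes for each sex and the gene's per-treatment status. It
#' round-trips losslessly through [read_truth()].
#'
#' @param truth A `GroundTruth` (or its `$table`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  table <- if (inherits(truth, "GroundTruth")) truth$table else truth
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a simulated cohort, its truth and its config to a directory
#'
#' Emits the gene-level expression table, sample sheet, probe table
#' and map (when present), truth ledger (`truth.tsv`), planted
#' pathways (`pathways.gmt`) and a flat key=value `config.txt`.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory.
#' @return Invisibly, the list returned by [generate_cohort()].
#' @export
simulate_to_dir <- function(config, dir) {
  sim <- generate_cohort(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, dir)
  write_truth(sim$truth, file.path(dir, "truth.tsv"))
  write_gmt(sim$truth$pathways, file.path(dir, "pathways.gmt"))
  flat <- vapply(config, function(v) paste(v, collapse = ","), "")
  writeLines(paste0(names(flat), "=", flat), file.path(dir, "config.txt"))
  invisible(sim)
}

#' Write pathway gene sets as a GMT file
#'
#' @param pathways Named list of gene-id vectors.
#' @param path Output `.gmt` path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, nm, pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
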