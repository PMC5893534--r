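# Shared fixtures and independent oracles for the suite.

# Small hand-built cohort: 3 genes, one sex, two conditions x 4 replicas.
toy_cohort <- function() {
  values <- rbind(
    gA = c(10, 11, 9, 10, 20, 22, 18, 20),
    gB = c(5, 5, 5, 5, 5, 5, 5, 5),
    gC = c(1, 1.2, 0.9, 1.1, 0.5, 0.55, 0.45, 0.5))
  colnames(values) <- paste0("s", 1:8)
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    sex = "male",
    condition = rep(c("BNS", "BYS"), each = 4),
    replica = rep(1:4, 2))
  expression_cohort(values, samples)
}

# Small, fast simulation config (no probe table unless asked).
small_config <- function(n_genes = 400, seed = 1,
                         conditions = c("BNS", "BYS", "BYA", "BYP"),
                         ...) {
  cohort_config(n_genes = n_genes, seed = seed, conditions = conditions,
                probes_per_gene = c(1L, 1L),
                frac_female_missing = 0,
                pathway_size = c(20L, 40L), ...)
}

# Independent regulation-call oracle: plain enumeration of the joint
# ratio-and-p criterion, one scalar at a time.
call_oracle <- function(x, cut, p, alpha = 0.05) {
  if (p >= alpha) return("X")
  if (x > 0 && x >= cut) return("U")
  if (x < 0 && -x >= cut) return("D")
  "X"
}
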