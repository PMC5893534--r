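test_that("pathway percentages use quantified pathway genes as denominator", {
  calls <- data.frame(gene = sprintf("g%02d", 1:10),
                      call = c("U", "U", "U", "D", "D", rep("X", 5)))
  expect_equal(pathway_percentages(calls),
               c(pct_up = 30, pct_down = 20))
  expect_equal(pathway_percentages(calls, "g04"),
               c(pct_up = 0, pct_down = 100))
  all_x <- data.frame(gene = "g1", call = "X")
  expect_equal(pathway_percentages(all_x), c(pct_up = 0, pct_down = 0))
  expect_error(pathway_percentages(calls, "nope"), "no pathway gene")
})

test_that("WPR reproduces hand-evaluated substitutions", {
  one <- data.frame(gene = "g1", mu_ref = 2, x = -3, p = 0.01)
  expect_equal(wpr(one), 2 * (3 - 1) * 0.99)  # 3.96
  two <- data.frame(gene = c("g1", "g2"), mu_ref = c(1, 1),
                    x = c(2, 1), p = c(0, 1))
  expect_equal(wpr(two), 0.5)
  flat <- data.frame(gene = c("g1", "g2"), mu_ref = c(5, 9),
                     x = c(1, -1), p = c(0.2, 0.01))
  expect_equal(wpr(flat), 0)
  expect_error(wpr(one, genes = "g9"), "no pathway gene")
})

test_that("WPR is non-negative and scale-equivariant in the reference means", {
  set.seed(7)
  contrasts <- data.frame(
    gene = sprintf("g%03d", 1:50),
    mu_ref = runif(50, 0.1, 5),
    x = signed_fold_change(runif(50, 0.5, 4), runif(50, 0.5, 4)),
    p = runif(50))
  w <- wpr(contrasts)
  expect_gte(w, 0)
  scaled <- contrasts
  scaled$mu_ref <- contrasts$mu_ref * 3.7
  expect_equal(wpr(scaled), 3.7 * w)
})

test_that("GER balances restored genes against side effects", {
  tt <- function(...) {
    out <- setNames(rep(0L, 9), TRANSITION_CLASSES)
    args <- c(...)
    out[names(args)] <- args
    out
  }
  expect_equal(ger(tt(DX = 10, UX = 5)), 100)
  expect_equal(ger(tt(XD = 4, XU = 6)), -100)
  expect_equal(ger(tt(DX = 3, XU = 1, DD = 4)), 25)
  expect_warning(g <- ger(tt(XX = 100)), "not applicable")
  expect_true(is.na(g))
  # attainment of the bounds
  expect_equal(ger(tt(DX = 1, UX = 7)), 100)
  expect_lt(ger(tt(DX = 10, UX = 5, DD = 1)), 100)
})

test_that("PRE reproduces the four outcome classes", {
  expect_equal(pre(0, 5), 100)        # full recovery
  p <- pre(2, 5)
  expect_true(p > 0 && p < 100)       # positive effect
  expect_equal(pre(5, 5), 0)          # null effect
  expect_equal(pre(10, 5), -100)      # negative effect
  expect_warning(na <- pre(1, 0), "not applicable")
  expect_true(is.na(na))
  expect_error(pre(-1, 5), "non-negative")
})

test_that("treatment comparison equals the reference Welch test", {
  expect_equal(compare_treatments(c(50, 60, 70, 80, 90),
                                  c(50, 60, 70, 80, 90)), 1)
  a <- c(90, 90.1, 89.9, 90, 90.05)
  b <- c(10, 10.1, 9.9, 10, 10.05)
  expect_lt(compare_treatments(a, b), 0.001)
  u <- c(58, 31, 23, 22, 33)
  v <- c(69, 44, 35, 30, 41)
  expect_equal(compare_treatments(u, v),
               t.test(u, v, var.equal = FALSE)$p.value, tolerance = 1e-10)
  expect_equal(compare_treatments(u, v, paired = TRUE),
               t.test(u, v, paired = TRUE)$p.value, tolerance = 1e-10)
  expect_error(compare_treatments(1, c(1, 2)), ">= 2 pathway scores")
})

test_that("ANOVA power is monotone and the search stops at the target", {
  expect_equal(anova_sample_size(f = 10, k = 3), 2)
  pw <- anova_power(2:12, f = 0.5, k = 4)
  expect_true(all(diff(pw) > 0))
  n <- anova_sample_size(f = 0.5, k = 4)
  expect_gte(anova_power(n, f = 0.5, k = 4), 0.80)
  expect_lt(anova_power(n - 1, f = 0.5, k = 4), 0.80)
  expect_error(anova_sample_size(f = 1e-4, k = 3, n_max = 50),
               "not reached")
})

test_that("GMT files round-trip and the shipped synapse sets load", {
  gmt <- read_gmt(system.file("extdata", "synapse_pathways.gmt",
                              package = "pathfabric"))
  expect_setequal(names(gmt), c("GLU", "ACH", "5HT", "GABA", "DA"))
  expect_true("Gad1" %in% gmt$GABA)

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gmt, path)
  expect_equal(read_gmt(path), gmt)
})

test_that("score_pathways assembles a coherent per-pathway table", {
  sim <- generate_cohort(small_config(n_genes = 300, seed = 13))
  co <- normalize_median(sim$cohort)
  res <- score_pathways(co, "male", sim$truth$pathways)
  sc <- res$scores
  expect_setequal(unique(sc$pathway), c("ALL", names(sim$truth$pathways)))
  expect_setequal(unique(sc$condition), c("BYS", "BYA", "BYP"))
  expect_true(all(sc$wpr >= 0))
  expect_true(all(sc$pre <= 100, na.rm = TRUE))
  expect_true(all(is.na(sc$ger[sc$condition == "BYS"])))
  expect_true(all(sc$pct_up + sc$pct_down <= 100))
  # ALL rows cover every quantified gene
  expect_equal(unique(sc$n_genes[sc$pathway == "ALL"]),
               nrow(res$calls$BYS))
})
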