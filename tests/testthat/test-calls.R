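test_that("signed fold-change follows the ratio convention", {
  expect_equal(signed_fold_change(2, 1), 2)
  expect_equal(signed_fold_change(1, 1), 1)   # equal means: the ">=" branch
  expect_equal(signed_fold_change(1, 4), -4)
  expect_error(signed_fold_change(0, 1), "positive")

  # antisymmetry whenever the means differ
  set.seed(1)
  a <- runif(200, 0.1, 10)
  b <- runif(200, 0.1, 10)
  diff <- a != b
  expect_equal(signed_fold_change(a, b)[diff],
               -signed_fold_change(b, a)[diff])
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})

test_that("the adaptive cut-off pools the four CVs", {
  expect_equal(adaptive_cutoff(0, 0, 0, 0), 1)
  expect_equal(adaptive_cutoff(0.3, 0.4, 0, 0), 1.5)
  expect_equal(adaptive_cutoff(0.1, 0.1, 0.1, 0.1), 1.2)
  expect_error(adaptive_cutoff(-0.1, 0), "non-negative")
  # monotone non-decreasing in every argument
  base <- adaptive_cutoff(0.1, 0.2, 0.05, 0.05)
  expect_gte(adaptive_cutoff(0.2, 0.2, 0.05, 0.05), base)
  expect_gte(adaptive_cutoff(0.1, 0.3, 0.05, 0.05), base)
  expect_gte(adaptive_cutoff(0.1, 0.2, 0.10, 0.05), base)
  expect_gte(adaptive_cutoff(0.1, 0.2, 0.05, 0.10), base)
})

test_that("Welch p matches the reference implementation and its invariances", {
  expect_equal(welch_p(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(welch_p(c(2, 2, 2), c(2, 2, 2)), 1)  # both constant, equal

  a <- c(1.0, 1.1, 0.9, 1.0)
  b <- c(2.0, 2.2, 1.8, 2.0)
  p <- welch_p(a, b)
  expect_lt(p, 0.001)
  ref <- t.test(log2(a), log2(b), var.equal = FALSE)$p.value
  expect_equal(p, ref, tolerance = 1e-10)

  # symmetric in the two samples; invariant under common rescaling
  expect_equal(welch_p(b, a), p, tolerance = 1e-12)
  expect_equal(welch_p(7.3 * a, 7.3 * b), p, tolerance = 1e-12)

  expect_error(welch_p(1, c(1, 2)), ">= 2 values")
  expect_error(welch_p(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("regulation calls equal the brute-force truth table", {
  expect_equal(call_regulation(2.0, 1.5, 0.01), "U")
  expect_equal(call_regulation(-2.0, 1.5, 0.20), "X")
  expect_equal(call_regulation(1.5, 1.5, 0.01), "U")   # boundary counts

  grid <- expand.grid(x = c(-1.6, -1.4, -1, 1, 1.4, 1.6),
                      p = c(0.01, 0.10))
  got <- call_regulation(grid$x, rep(1.5, nrow(grid)), grid$p)
  want <- mapply(call_oracle, grid$x, 1.5, grid$p)
  expect_equal(got, unname(want))

  # wider randomized grid against the same oracle
  set.seed(42)
  x <- signed_fold_change(runif(300, 0.2, 5), runif(300, 0.2, 5))
  cut <- 1 + runif(300, 0, 1)
  p <- runif(300)
  expect_equal(call_regulation(x, cut, p),
               unname(mapply(call_oracle, x, cut, p)))
})

test_that("transition classes are the nine-way product of calls", {
  expect_equal(classify_transition("D", "X"), "DX")
  expect_equal(classify_transition("X", "U"), "XU")
  pairs <- expand.grid(a = c("U", "D", "X"), b = c("U", "D", "X"),
                       stringsAsFactors = FALSE)
  classes <- classify_transition(pairs$a, pairs$b)
  expect_setequal(classes, TRANSITION_CLASSES)
  expect_equal(anyDuplicated(classes), 0L)
  expect_error(classify_transition("Z", "X"), "U, D, X")
})

test_that("transition tables count every shared gene exactly once", {
  d <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  call = c("D", "U", "X", "D"))
  t <- data.frame(gene = c("g2", "g3", "g4", "g5"),
                  call = c("X", "D", "D", "U"))
  tt <- transition_table(d, t)
  expect_s3_class(tt, "TransitionTable")
  expect_equal(sum(tt), 3L)  # g1 and g5 are not shared
  expect_equal(tt[["UX"]], 1L)
  expect_equal(tt[["XD"]], 1L)
  expect_equal(tt[["DD"]], 1L)
})

test_that("contrast calls are equivariant under gene reordering", {
  sim <- generate_cohort(small_config(n_genes = 80, seed = 21))
  co <- normalize_median(sim$cohort)
  calls <- contrast_calls(co, "male", "BYS")

  perm <- sample(nrow(co$values))
  co2 <- co
  co2$values <- co$values[perm, , drop = FALSE]
  calls2 <- contrast_calls(co2, "male", "BYS")
  calls2 <- calls2[match(calls$gene, calls2$gene), ]
  rownames(calls2) <- NULL
  expect_equal(calls2, calls)
})

test_that("calls on a clean simulation recover the planted directions", {
  cfg <- small_config(n_genes = 500, seed = 31,
                      biological_cv = c(0.05, 0.15),
                      effect_fc_range = c(2.5, 4))
  sim <- generate_cohort(cfg)
  calls <- contrast_calls(normalize_median(sim$cohort), "male", "BYS")
  truth <- sim$truth$table[sim$truth$table$condition == "BYS", ]
  fc <- truth$fc_male[match(calls$gene, truth$gene)]
  up <- fc > 1
  down <- fc < 0
  expect_gt(mean(calls$call[up] == "U"), 0.9)
  expect_gt(mean(calls$call[down] == "D"), 0.9)
  expect_lt(mean(calls$call[fc == 1] != "X"), 0.08)
})
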