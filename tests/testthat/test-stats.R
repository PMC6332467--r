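# Exact tests, residual post-hoc, ANOVA, Dunnett and Bonferroni, checked
# against base-R and mvtnorm/multcomp oracles.

test_that("fisher_exact_2x2 matches fisher.test on random and printed tables", {
  printed <- list(
    list(m = matrix(c(65, 35, 58, 57), 2, byrow = TRUE), p = 0.038),
    list(m = matrix(c(22, 27, 3, 5), 2, byrow = TRUE), p = 1),
    list(m = matrix(c(14, 28, 4, 9), 2, byrow = TRUE), p = 1),
    list(m = matrix(c(26, 28, 2, 4), 2, byrow = TRUE), p = 0.675))
  for (case in printed) {
    got <- fisher_exact_2x2(case$m)
    expect_equal(round(got$p.value, 3), case$p)
    expect_equal(got$p.value, fisher.test(case$m)$p.value, tolerance = 1e-10)
  }
  set.seed(404)
  for (i in 1:25) {
    m <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p.value, fisher.test(m)$p.value,
                 tolerance = 1e-10, label = paste(m, collapse = ","))
  }
})

test_that("fisher_exact_2x2 handles degenerate and balanced tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p.value, 1)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2, byrow = TRUE))
  expect_equal(deg$p.value, 1)
  expect_true(deg$degenerate)
})

test_that("fisher_exact_2x2 is invariant to permutation and transposition", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(4, 15) + 1, 2)
    p <- fisher_exact_2x2(m)$p.value
    expect_equal(fisher_exact_2x2(m[2:1, ])$p.value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m[, 2:1])$p.value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(m))$p.value, p, tolerance = 1e-12)
  }
})

test_that("freeman_halton_exact reproduces printed 3x2 p-values exactly", {
  t5 <- list(
    list(m = matrix(c(41, 57, 30, 31, 29, 27), 3, byrow = TRUE), p = 0.434),
    list(m = matrix(c(42, 57, 22, 31, 36, 27), 3, byrow = TRUE), p = 0.134),
    list(m = matrix(c(35, 57, 31, 31, 34, 27), 3, byrow = TRUE), p = 0.083))
  for (case in t5) {
    got <- freeman_halton_exact(case$m)
    expect_equal(got$method, "full-enumeration")
    expect_equal(round(got$p.value, 3), case$p)
    expect_equal(got$p.value, fisher.test(case$m)$p.value, tolerance = 1e-7)
  }
})

test_that("freeman_halton_exact reduces to the 2x2 test", {
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rpois(4, 12) + 1, 2)
    expect_equal(freeman_halton_exact(m)$p.value,
                 fisher_exact_2x2(m)$p.value, tolerance = 1e-12)
  }
})

test_that("enumeration probabilities sum to one and Monte Carlo agrees", {
  set.seed(21)
  for (i in 1:6) {
    m <- matrix(rpois(6, 8) + 1, 3)  # 3x2, N around 50
    rs <- rowSums(m); cs <- colSums(m)
    lobs <- mitoload:::fh_log_base(rs, cs) - sum(lfactorial(m))
    enum <- mitoload:::fh_enumerate(rs, cs, lobs, cap = 1e6)
    expect_true(enum$complete)
    expect_equal(enum$total, 1, tolerance = 1e-9)
    exact <- freeman_halton_exact(m)
    mc <- freeman_halton_exact(m, max_enumeration = 1, mc_replicates = 2e4,
                               seed = 100 + i)
    expect_equal(mc$method, "monte-carlo")
    expect_lt(abs(mc$p.value - exact$p.value), 3 * mc$std.error + 1e-3)
  }
})

test_that("freeman_halton_exact enforces the replicate floor", {
  expect_error(freeman_halton_exact(matrix(1:4, 2), mc_replicates = 10),
               "mc_replicates")
})

test_that("adjusted residuals reproduce the published haplogroup signals", {
  tab <- study_hap_table()
  pair <- function(d) {
    m <- tab[, c(d, "control")]
    m[rowSums(m) > 0, , drop = FALSE]
  }
  r1 <- adjusted_residuals(pair("t2dm"))
  expect_equal(round(r1$residuals["V", "t2dm"], 2), -2.18)
  expect_equal(round(r1$phi["V", "t2dm"], 3), -0.148)
  expect_equal(round(r1$p.value["V", "t2dm"], 5), 0.02961, tolerance = 1e-4)
  r2 <- adjusted_residuals(pair("obesity"))
  expect_equal(round(r2$residuals["U", "obesity"], 2), -2.60)
  expect_equal(round(r2$phi["U", "obesity"], 3), -0.177)
  r3 <- adjusted_residuals(pair("atherosclerosis"))
  expect_equal(round(r3$residuals["U", "atherosclerosis"], 2), -1.99)
  expect_equal(round(r3$phi["U", "atherosclerosis"], 3), -0.136)
})

test_that("adjusted residuals satisfy their algebraic identities", {
  set.seed(33)
  for (i in 1:8) {
    m <- matrix(rpois(12, 10) + 1, 4)
    r <- adjusted_residuals(m)
    expect_equal(rowSums(r$observed - r$expected), rep(0, 4),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(colSums(r$observed - r$expected), rep(0, 3),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(r$phi, r$residuals / sqrt(sum(m)))
  }
  # 2x2: |r| identical across cells, equal to sqrt of uncorrected chi-square
  for (i in 1:8) {
    m <- matrix(rpois(4, 20) + 1, 2)
    r <- adjusted_residuals(m)
    expect_equal(max(abs(r$residuals)) - min(abs(r$residuals)), 0,
                 tolerance = 1e-10)
    chi <- suppressWarnings(chisq.test(m, correct = FALSE)$statistic)
    expect_equal(abs(r$residuals[1, 1]), sqrt(unname(chi)),
                 tolerance = 1e-10)
    expect_equal(r$phi[1, 1], sign(r$residuals[1, 1]) *
                   sqrt(unname(chi) / sum(m)), tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches the base-R oracle on raw data", {
  set.seed(5)
  for (i in 1:5) {
    groups <- lapply(sample(3:6, 4, TRUE) + 3, rnorm)
    a <- anova_oneway_raw(groups)
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ow <- oneway.test(y ~ g, var.equal = TRUE)
    expect_equal(unname(a$statistic), unname(ow$statistic),
                 tolerance = 1e-10)
    expect_equal(a$p.value, ow$p.value, tolerance = 1e-10)
    expect_equal(a$df, unname(unlist(ow$parameter)), ignore_attr = TRUE)
    # summary form on the exact summaries is identical
    s <- anova_oneway_summary(vapply(groups, length, 0L),
                              vapply(groups, mean, 0),
                              vapply(groups, sd, 0))
    expect_equal(s$statistic, a$statistic)
    expect_equal(s$p.value, a$p.value)
  }
})

test_that("ANOVA handles identical and degenerate groups", {
  g <- rnorm(10)
  a <- anova_oneway_raw(list(g, g))
  expect_equal(a$statistic, 0, tolerance = 1e-12)
  expect_equal(a$p.value, 1, tolerance = 1e-10)
  expect_equal(anova_oneway_summary(c(5, 5), c(1, 1), c(1, 2))$statistic, 0)
  d <- anova_oneway_summary(c(5, 5), c(1, 2), c(0, 0))
  expect_true(d$degenerate)
  expect_true(is.na(d$p.value))
  expect_error(anova_oneway_summary(c(5, 5), c(1, 2, 3), c(1, 1)), "length")
})

test_that("Dunnett with one comparison equals the pooled two-sample t-test", {
  set.seed(17)
  a <- rnorm(20, 0.4); b <- rnorm(25)
  d <- dunnett_two_tailed(list(trt = a, ctl = b), control_index = 2,
                          mc_replicates = 2e5, seed = 3)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_lt(abs(d$comparisons$p.adjust - tt$p.value),
            3 * d$comparisons$mc.std.error + 2e-3)
  expect_equal(unname(d$comparisons$t), unname(tt$statistic),
               tolerance = 1e-10)
})

test_that("Dunnett agrees with the multcomp/mvtnorm oracle", {
  skip_if_not_installed("multcomp")
  set.seed(29)
  groups <- list(a = rnorm(20, 0.6), b = rnorm(25, 0.2),
                 c = rnorm(18, -0.4), control = rnorm(30))
  d <- dunnett_two_tailed(groups, control_index = 4, mc_replicates = 2e5,
                          seed = 19)
  y <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)),
              levels = c("control", "a", "b", "c"))
  fit <- stats::aov(y ~ g)
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  p_oracle <- as.numeric(gl$test$pvalues)
  for (j in 1:3)
    expect_lt(abs(d$comparisons$p.adjust[j] - p_oracle[j]),
              max(0.01, 4 * d$comparisons$mc.std.error[j]))
})

test_that("Dunnett adjusted p dominates the pairwise p and is monotone", {
  set.seed(41)
  groups <- list(rnorm(15, 0.8), rnorm(15, 0.1), rnorm(15, -0.5), rnorm(20))
  d <- dunnett_two_tailed(groups, control_index = 4, mc_replicates = 1e5,
                          seed = 23)
  for (j in 1:3) {
    pt <- t.test(groups[[j]], groups[[4]], var.equal = TRUE)$p.value
    expect_gt(d$comparisons$p.adjust[j] + 3 * d$comparisons$mc.std.error[j],
              pt)
  }
  ord <- order(abs(d$comparisons$t))
  expect_equal(order(d$comparisons$p.adjust[ord], decreasing = TRUE), 1:3)
  # identical groups: all adjusted p near 1
  g <- rnorm(12)
  same <- dunnett_two_tailed(list(g, g + 1e-12, g), control_index = 3,
                             mc_replicates = 1e5, seed = 5)
  expect_true(all(same$comparisons$p.adjust > 0.99))
})

test_that("Dunnett rejects invalid designs", {
  expect_error(dunnett_two_tailed(list(rnorm(5), rnorm(1)),
                                  control_index = 2,
                                  mc_replicates = 1e5), "n >= 2")
  expect_error(dunnett_two_tailed(list(rnorm(5), rnorm(5)),
                                  mc_replicates = 100), "1e5")
})

test_that("Bonferroni correction caps and scales", {
  expect_equal(bonferroni_adjust(0.02961, m = 15), 0.44415)
  expect_equal(bonferroni_adjust(0.5, m = 2), 1)
  expect_equal(bonferroni_adjust(0, m = 100), 0)
  expect_equal(bonferroni_adjust(c(0.01, 0.04), m = 3), c(0.03, 0.12))
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "at least")
  expect_error(bonferroni_adjust(1.2), "0, 1")
})

test_that("contingency_table validates shape and counts", {
  expect_error(contingency_table(matrix(1:3, 1)), "2x2")
  expect_error(contingency_table(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(contingency_table(matrix(0L, 2, 2)), "positive")
  m <- contingency_table(matrix(1:4, 2), row_labels = c("a", "b"))
  expect_equal(rownames(m), c("a", "b"))
})
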