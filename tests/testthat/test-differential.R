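test_that("one-way ANOVA p-values match the classical F computation", {
  # 3 groups of sizes 5/10/7 with fixed printed values
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1,
         0.1, -0.2, 0.4, 0.0, 0.3, -0.1, 0.2, -0.3, 0.5, 0.1,
         1.8, 2.1, 1.6, 2.4, 1.9, 2.2, 1.7)
  g <- rep(c("poor", "normal", "long_term"), c(5, 10, 7))
  co <- toy_cohort(c(runif(5, 1, 2.9), runif(10, 4, 22), runif(7, 25, 40)))
  m <- toy_matrix(matrix(x, ncol = 1), samples = co$patient_id)
  p <- anova_by_group(m, co)

  # textbook F-statistic as the oracle
  k <- 3; n <- length(x)
  gm <- tapply(x, g, mean)
  ssb <- sum(table(g) * (gm[names(table(g))] - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(unname(p), pf(f, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-10)
  # agrees with stats::aov on the same data
  pa <- summary(stats::aov(x ~ factor(g)))[[1]][["Pr(>F)"]][1]
  expect_equal(unname(p), pa, tolerance = 1e-10)

  # identical within-group samples, equal means -> F = 0, p = 1
  xx <- rep(c(1, 2, 3), each = 3)
  co3 <- toy_cohort(c(1, 10, 30, 2, 15, 28, 2.5, 20, 26))
  m3 <- toy_matrix(matrix(xx, ncol = 1), samples = co3$patient_id)
  expect_equal(unname(anova_by_group(m3, co3)), 1)

  # extreme separation
  sep <- c(rep(0, 5) + rnorm(5, sd = 0.01), rep(10, 5) + rnorm(5, sd = 0.01))
  cos <- toy_cohort(c(runif(5, 1, 2.9), runif(5, 25, 40)))
  ms <- toy_matrix(matrix(sep, ncol = 1), samples = cos$patient_id)
  expect_lt(unname(anova_by_group(ms, cos)), 1e-6)
})

test_that("pairwise fold changes and Welch p-values match closed forms", {
  set.seed(11)
  a <- rnorm(7, 1); b <- rnorm(10)
  co <- toy_cohort(c(runif(10, 4, 22), runif(7, 25, 40)))
  m <- toy_matrix(matrix(c(b, a), ncol = 1), samples = co$patient_id)
  ps <- pairwise_stats(m, co, c("long_term", "normal"))
  expect_equal(ps$fc, mean(a) - mean(b), tolerance = 1e-12)

  # Welch-Satterthwaite oracle
  va <- var(a) / 7; vb <- var(b) / 10
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / 6 + vb^2 / 9)
  expect_equal(ps$p, 2 * pt(-abs(tstat), df), tolerance = 1e-10)

  # identical groups: fc 0, p 1
  co2 <- toy_cohort(c(runif(4, 4, 22), runif(4, 25, 40)))
  m2 <- toy_matrix(matrix(rep(c(1, 2, 3, 4), 2), ncol = 1),
                   samples = co2$patient_id)
  ps2 <- pairwise_stats(m2, co2, c("long_term", "normal"))
  expect_equal(ps2$fc, 0)
  expect_equal(ps2$p, 1)

  # student-t and rank options return valid probabilities
  for (tt in c("student_t", "mann_whitney")) {
    pp <- pairwise_stats(m, co, c("long_term", "normal"), test = tt)$p
    expect_true(pp >= 0 && pp <= 1)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:250) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))  # force ties sometimes
    expect_equal(benjamini_hochberg(p), oracle_bh(p))
  }
  # permutation equivariance and NA pass-through
  p <- c(0.4, NA, 0.01, 0.7, 0.01)
  q <- benjamini_hochberg(p)
  expect_true(is.na(q[2]))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(benjamini_hochberg(p[perm]), q[perm])
})

test_that("the signature rule filters on p and concordant signs, ranked by p", {
  rec <- data.frame(
    protein_id = sprintf("X%02d", 1:24),
    p_long_vs_normal = c(seq(0.001, 0.095, length.out = 20),
                         0.05, 0.2, 0.3, 0.01),
    fc_long_vs_normal = c(rep(1, 20), 1, 1, -1, -0.5),
    fc_long_vs_poor = c(rep(2, 20), -1, 1, -1, -0.25))
  sig <- select_de_signature(rec)
  # X21 has discordant signs, X22/X23 exceed p threshold; X24 is concordant
  # negative and has the second-smallest p
  expect_length(sig, 15L)
  expect_false("X21" %in% sig)
  expect_false(any(c("X22", "X23") %in% sig))
  expect_equal(sig[1:4], c("X01", "X02", "X24", "X03"))
  # exactly the smallest-p eligible proteins, in p order
  eligible <- rec[rec$p_long_vs_normal < 0.1 &
                    sign(rec$fc_long_vs_normal) == sign(rec$fc_long_vs_poor), ]
  expect_equal(sig, eligible$protein_id[order(eligible$p_long_vs_normal)][1:15])

  # deterministic tie-break: larger |fc| first, then id
  tie <- data.frame(protein_id = c("B", "A", "C"),
                    p_long_vs_normal = c(0.02, 0.02, 0.02),
                    fc_long_vs_normal = c(1, 1, 2),
                    fc_long_vs_poor = c(1, 1, 1))
  expect_equal(select_de_signature(tie, top_k = 2), c("C", "A"))
})

test_that("differential records are complete and internally consistent", {
  sim <- generate_cohort(synthetic_spec(effect_long_vs_normal = 1.5), seed = 4)
  det <- filter_detected(sim$matrix)
  de <- differential_expression(det, sim$cohort)
  expect_equal(nrow(de), 126L)
  expect_true(all(de$q_anova >= de$p_anova - 1e-12, na.rm = TRUE))
  expect_true(!is.unsorted(de$p_long_vs_normal, na.rm = TRUE))
  sig <- attr(de, "signature")
  expect_lte(length(sig), 15L)
  expect_true(all(de$selected[de$protein_id %in% sig]))
  sel <- de[de$selected, ]
  expect_true(all(sel$p_long_vs_normal < 0.1))
  expect_true(all(sign(sel$fc_long_vs_normal) == sign(sel$fc_long_vs_poor)))
  # the planted majority is found in this cohort
  expect_gte(sum(sim$truth$signal_proteins %in% sig), 4L)
})
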