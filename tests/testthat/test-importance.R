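# naive breakpoint-search oracle for the two-piece exponential profile:
# for every candidate breakpoint (each observed value), compute the
# piecewise-constant-hazard log-likelihood directly from its definition
oracle_two_piece <- function(x) {
  xs <- sort(x)
  m <- length(xs)
  best <- list(ll = -Inf, thr = NA)
  for (c0 in unique(xs[-m])) {
    d1 <- sum(xs <= c0); d2 <- m - d1
    t1 <- sum(pmin(xs, c0)); t2 <- sum(pmax(xs - c0, 0))
    if (t1 <= 0 || t2 <= 0 || d1 < 1 || d2 < 1) next
    l1 <- d1 / t1; l2 <- d2 / t2
    if (l2 >= l1) next                      # tail must decay more slowly
    ll <- d1 * log(l1) - l1 * t1 + d2 * log(l2) - l2 * t2
    if (ll > best$ll) best <- list(ll = ll, thr = c0)
  }
  best
}

test_that("the profile breakpoint equals an exhaustive naive search", {
  set.seed(17)
  for (i in 1:40) {
    x <- c(rexp(sample(10:60, 1)), rexp(sample(2:8, 1), rate = 0.05))
    got <- plasmasig:::two_piece_profile(x)
    want <- oracle_two_piece(x)
    expect_equal(unname(got$threshold), want$thr)
    expect_equal(unname(got$loglik2), want$ll, tolerance = 1e-10)
  }
})

test_that("a clear importance gap selects exactly the high tier", {
  imp <- setNames(c(10, 9.5, 9, 0.1, 0.09, 0.08, 0.07), paste0("p", 1:7))
  cut <- survivor_rate_change_cutoff(imp)
  expect_setequal(cut$selected, c("p1", "p2", "p3"))
  expect_true(cut$threshold >= 0.1 && cut$threshold < 9)
  expect_lte(cut$p_value, 0.05)

  expect_error(survivor_rate_change_cutoff(c(a = 1, b = 2)), "3 distinct")
  expect_warning(out <- survivor_rate_change_cutoff(rep(0, 5)), "zero")
  expect_length(out$selected, 0L)

  # heuristic variant also finds the gap
  h <- survivor_rate_change_cutoff(imp, method = "second_diff")
  expect_true(all(c("p1", "p2", "p3") %in% h$selected))
})

test_that("i.i.d. exponential importances rarely trigger a selection", {
  empty <- vapply(1:200, function(s) {
    x <- setNames(with(list(), {set.seed(s); rexp(126)}), paste0("q", 1:126))
    length(survivor_rate_change_cutoff(x, n_boot = 99, seed = s)$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("penalized importances are invariant to column order for a fixed split", {
  set.seed(41)
  X <- matrix(rnorm(12 * 30), 12, 30, dimnames = list(NULL, sprintf("P%02d", 1:30)))
  y <- rep(c(0, 1), each = 6)
  perm <- sample(30)
  for (alpha in c(1, 0, 0.5)) {
    set.seed(99)
    a <- plasmasig:::fit_penalized_importance(X, y, alpha)
    set.seed(99)
    b <- plasmasig:::fit_penalized_importance(X[, perm], y, alpha)
    unperm <- numeric(30); unperm[perm] <- b
    # agreement is bounded by the coordinate-descent solver tolerance, not
    # by floating-point arithmetic
    expect_lt(max(abs(a - unperm)), 1e-3)
    expect_equal(order(-a)[1:3], order(-unperm)[1:3])
  }
})

test_that("a strongly planted protein dominates every learner's importance", {
  top_all <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 17
    y <- c(rep(1, 7), rep(0, 10))
    X <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, sprintf("P%02d", 1:40)))
    X[, 7] <- X[, 7] + 3 * y        # 3 SD standardized effect
    m <- zscore_normalize(expression_matrix(X, sample_ids = sprintf("S%02d", 1:n)))
    imp <- run_importance_trials(m, y, n_orders = 4, n_cv = 10, seed = s)
    all(vapply(split(imp, imp$learner), function(d)
      d$protein_id[which.max(d$mean_importance)] == "P07", logical(1)))
  }, logical(1))
  expect_gte(mean(top_all), 0.9)
})

test_that("importance trials are reproducible and correctly shaped", {
  sim <- generate_cohort(synthetic_spec(n_proteins_monitored = 30,
                                        n_proteins_detected = 30,
                                        n_signal = 2), seed = 2)
  det <- zscore_normalize(impute_missing(filter_detected(sim$matrix)))
  g <- sim$cohort$group[match(rownames(det), sim$cohort$patient_id)]
  keep <- g %in% c("long_term", "normal")
  y <- as.integer(g[keep] == "long_term")
  a <- run_importance_trials(det[keep, ], y, n_orders = 2, n_cv = 3, seed = 7)
  b <- run_importance_trials(det[keep, ], y, n_orders = 2, n_cv = 3, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 30L * 4L)
  expect_true(all(a$mean_importance >= 0))
  expect_true(all(a$n_trials == 6L))

  expect_error(run_importance_trials(det[keep, ], y, learners = "svm"),
               "learners")
  expect_error(run_importance_trials(det[1:3, ], c(1, 1, 0)), "2 members")
})

test_that("single-learner selection equals the combined set (union of one)", {
  sim <- generate_cohort(synthetic_spec(n_proteins_monitored = 25,
                                        n_proteins_detected = 25,
                                        n_signal = 2,
                                        effect_long_vs_normal = 2,
                                        effect_long_vs_poor = 2), seed = 9)
  det <- filter_detected(sim$matrix)
  sel <- select_candidates(det, sim$cohort, learners = "lasso",
                           contrasts = list(c("long_term", "normal")),
                           n_orders = 2, n_cv = 5, seed = 3)
  expect_identical(sel$combined,
                   sort(sel$long_term_vs_normal$cutoffs$lasso$selected))
  expect_identical(sel$combined, sel$long_term_vs_normal$union_selected)
})
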