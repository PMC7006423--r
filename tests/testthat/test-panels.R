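test_that("panel enumeration matches the closed-form binomial sums", {
  expect_length(enumerate_panels(c("a", "b", "c")), 7L)
  expect_length(enumerate_panels("solo"), 1L)
  for (n in c(1, 2, 3, 5, 10, 26, 52)) {
    ids <- sprintf("P%02d", seq_len(n))
    got <- enumerate_panels(ids, 3)
    want <- sum(choose(n, seq_len(min(3, n))))
    expect_length(got, want)
    expect_false(any(duplicated(vapply(got, paste, character(1),
                                       collapse = "+"))))
  }
  # panels come out sorted regardless of candidate order
  p1 <- enumerate_panels(c("b", "a", "c"), 2)
  p2 <- enumerate_panels(c("c", "b", "a"), 2)
  expect_identical(p1, p2)
})

test_that("AUC equals the pair-counting oracle, including ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)  # forces ties
    expect_equal(auc(s, y), oracle_auc(s, y))
  }
})

test_that("ROC vertical averaging matches hand computation", {
  c1 <- data.frame(specificity = c(1, 0.5, 0), sensitivity = c(0, 0.5, 1))
  c2 <- data.frame(specificity = c(1, 0.75, 0.25, 0),
                   sensitivity = c(0.2, 0.4, 0.8, 1))
  avg <- average_roc(list(c1, c2), grid = c(0, 0.25, 0.5, 0.75, 1))
  # step rule: best sensitivity at specificity >= g, averaged across curves
  expect_equal(avg$sensitivity,
               c((1 + 1) / 2, (0.5 + 0.8) / 2, (0.5 + 0.4) / 2,
                 (0 + 0.4) / 2, (0 + 0.2) / 2))
  # identical trials average to the single curve on the grid
  same <- average_roc(list(c1, c1), grid = c(0, 0.5, 1))
  expect_equal(same$sensitivity, c(1, 0.5, 0))
  # perfect trials sit at sensitivity 1 below specificity 1
  perf <- data.frame(specificity = c(1, 1, 0), sensitivity = c(0, 1, 1))
  expect_equal(average_roc(list(perf))$sensitivity, rep(1, 101))
})

test_that("optimism-corrected AUC behaves on a separable panel and is order-free", {
  set.seed(6)
  n <- 18
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("S%02d", 1:n),
                                                  c("A", "B", "C", "D")))
  y <- rep(c(0, 1), each = 9)
  X[, 2] <- X[, 2] + 2.5 * y
  m <- zscore_normalize(expression_matrix(X))
  rec <- optimism_corrected_auc(c("B", "A"), m, y, n_cv = 20, n_shuffles = 10,
                                seed = 11)
  expect_identical(rec$proteins, c("A", "B"))
  expect_true(all(rec$cv_aucs >= 0 & rec$cv_aucs <= 1))
  expect_true(rec$ci_low <= rec$corrected_auc_median)
  expect_true(rec$ci_high >= rec$corrected_auc_median)
  expect_gt(rec$corrected_auc_median, 0.8)
  # correction direction: corrected <= raw whenever the null median > 0.5
  idx <- rec$null_aucs > 0.5
  expect_true(all(rec$corrected_aucs[idx] <= rec$cv_aucs[idx] + 1e-12))
  # panel identity is order-free given the same seed
  rec2 <- optimism_corrected_auc(c("A", "B"), m, y, n_cv = 20,
                                 n_shuffles = 10, seed = 11)
  expect_identical(rec[names(rec) != "avg_roc"], rec2[names(rec2) != "avg_roc"])
  expect_equal(rec$avg_roc, rec2$avg_roc)

  expect_error(optimism_corrected_auc("ZZ", m, y), "absent")
})

test_that("contributions recount panel membership among high performers", {
  fake <- function(proteins, aucm)
    structure(list(proteins = sort(proteins), corrected_auc_median = aucm),
              class = "panel_record")
  cands <- c("a", "b", "c", "d", "e")
  panels <- enumerate_panels(cands, 2)
  set.seed(2)
  aucs <- runif(length(panels), 0.5, 1)
  records <- Map(fake, panels, aucs)
  ca <- contribution_analysis(records, auc_threshold = 0.85,
                              min_proportion = 0.05)
  high <- panels[aucs > 0.85]
  expect_equal(ca$n_high, length(high))
  for (i in seq_len(nrow(ca$table))) {
    pid <- ca$table$protein_id[i]
    expect_equal(ca$table$n_high_panels[i],
                 sum(vapply(high, function(p) pid %in% p, logical(1))))
  }
  expect_setequal(ca$contributing,
                  ca$table$protein_id[ca$table$proportion > 0.05])
  # protein absent from every high panel never contributes
  expect_false("zz" %in% ca$contributing)
  expect_warning(contribution_analysis(list(fake("a", 0.3))), "threshold")
})

test_that("the final signature combines the three lists with auditable rules", {
  fin <- final_signature(c("A", "B"), c("B", "C"), c("B"))
  expect_setequal(fin$final, c("A", "B", "C"))
  expect_equal(fin$top_candidates, "B")
  expect_equal(unname(fin$venn[c("D", "N", "DNP")]), c(1L, 1L, 1L))
  strict <- final_signature(c("A", "B"), c("B", "C"), c("B"), rule = "strict")
  expect_equal(strict$final, "B")

  disj <- final_signature(c("A"), c("B"), c("C"))
  expect_length(disj$top_candidates, 0L)
  expect_setequal(disj$final, c("A", "B", "C"))
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    y <- c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))
    s <- rnorm(n)
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(auc(s, y), ref, tolerance = 1e-12)
  }
})
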