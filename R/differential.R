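# Align an expression matrix with a grouped cohort: keeps samples present in
# both and with a known group, in matrix order.
align_groups <- function(matrix, cohort) {
  stopifnot(inherits(matrix, "expr_matrix"), "group" %in% names(cohort))
  keep <- rownames(matrix)[rownames(matrix) %in%
                             cohort$patient_id[!is.na(cohort$group)]]
  if (!length(keep)) stop("no samples shared between matrix and cohort")
  g <- cohort$group[match(keep, cohort$patient_id)]
  list(matrix = matrix[keep, , drop = FALSE], groups = droplevels(g),
       sample_ids = keep)
}

#' One-way ANOVA p-value per protein
#'
#' Classical fixed-effects one-way ANOVA of the effect of response group on
#' expression, computed per protein over its non-missing values. Proteins
#' with fewer than two groups having at least two observations get `NA`.
#'
#' @param matrix [expression_matrix()].
#' @param cohort grouped cohort (see [assign_response_groups()]).
#' @return Named numeric vector of p-values, one per protein.
#' @export
anova_by_group <- function(matrix, cohort) {
  al <- align_groups(matrix, cohort)
  if (nlevels(al$groups) < 2L) stop("fewer than 2 response groups present")
  vals <- unclass(al$matrix)
  g <- al$groups
  vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    ok <- !is.na(x)
    gg <- droplevels(g[ok])
    counts <- table(gg)
    if (sum(counts >= 2L) < 2L) return(NA_real_)
    use <- gg %in% names(counts)[counts >= 2L]
    x <- x[ok][use]; gg <- droplevels(gg[use])
    k <- nlevels(gg); n <- length(x)
    gm <- tapply(x, gg, mean)
    ssb <- sum(tabulate(gg) * (gm - mean(x))^2)
    ssw <- sum((x - gm[gg])^2)
    if (ssw == 0) {
      if (ssb == 0) return(1)
      return(0)
    }
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  }, numeric(1)) -> p
  stats::setNames(p, colnames(vals))
}

#' Pairwise fold change and p-value per protein
#'
#' Fold change is the difference of group means on the log2 scale (the log2
#' ratio of geometric means on the raw scale); the sign gives the direction.
#' The default test is Welch's two-sample t-test, robust to the unequal group
#' sizes and variances typical of n = 5-10 response groups.
#'
#' @param matrix [expression_matrix()].
#' @param cohort grouped cohort.
#' @param pair character of length 2, e.g. `c("long_term", "normal")`; fold
#'   change is mean(first) - mean(second).
#' @param test `"welch_t"`, `"student_t"` or `"mann_whitney"`.
#' @return data.frame with `protein_id`, `fc`, `p`, and the two group means.
#' @export
pairwise_stats <- function(matrix, cohort, pair = c("long_term", "normal"),
                           test = c("welch_t", "student_t", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(length(pair) == 2L, all(pair %in% response_levels))
  al <- align_groups(matrix, cohort)
  vals <- unclass(al$matrix)
  g <- al$groups
  res <- t(vapply(seq_len(ncol(vals)), function(j) {
    xa <- vals[g == pair[1L], j]; xa <- xa[!is.na(xa)]
    xb <- vals[g == pair[2L], j]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    fc <- mean(xa) - mean(xb)
    p <- switch(test,
      welch_t = stats::t.test(xa, xb, var.equal = FALSE)$p.value,
      student_t = stats::t.test(xa, xb, var.equal = TRUE)$p.value,
      mann_whitney = suppressWarnings(
        stats::wilcox.test(xa, xb, exact = FALSE)$p.value))
    c(fc, p, mean(xa), mean(xb))
  }, numeric(4)))
  data.frame(protein_id = colnames(vals), fc = res[, 1L], p = res[, 2L],
             mean_a = res[, 3L], mean_b = res[, 4L],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up false-discovery-rate adjustment; `NA` entries are passed
#' through untouched.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  names(q) <- names(pvals)
  q
}

#' Per-protein differential expression records
#'
#' Computes group means, log2 fold changes for the long-vs-normal and
#' long-vs-poor contrasts, the one-way ANOVA p-value with its BH q-value,
#' pairwise p-values, and the direction-consistent selection flag.
#'
#' @inheritParams pairwise_stats
#' @param p_threshold pairwise long-vs-normal p-value cutoff (default 0.1).
#' @param top_k signature size cap (default 15).
#' @return data.frame of differential records, sorted by `p_long_vs_normal`,
#'   with the selected signature in attribute `"signature"`.
#' @export
differential_expression <- function(matrix, cohort,
                                    test = c("welch_t", "student_t",
                                             "mann_whitney"),
                                    p_threshold = 0.1, top_k = 15) {
  test <- match.arg(test)
  al <- align_groups(matrix, cohort)
  vals <- unclass(al$matrix)
  g <- al$groups
  gmean <- function(lev) {
    if (!lev %in% levels(g)) return(rep(NA_real_, ncol(vals)))
    colMeans(vals[g == lev, , drop = FALSE], na.rm = TRUE)
  }
  lvn <- pairwise_stats(matrix, cohort, c("long_term", "normal"), test)
  lvp <- pairwise_stats(matrix, cohort, c("long_term", "poor"), test)
  p_anova <- anova_by_group(matrix, cohort)
  rec <- data.frame(
    protein_id = colnames(vals),
    mean_poor = gmean("poor"),
    mean_normal = gmean("normal"),
    mean_long = gmean("long_term"),
    fc_long_vs_normal = lvn$fc,
    fc_long_vs_poor = lvp$fc,
    p_anova = unname(p_anova),
    p_long_vs_normal = lvn$p,
    p_long_vs_poor = lvp$p,
    stringsAsFactors = FALSE)
  rec$q_anova <- benjamini_hochberg(rec$p_anova)
  sig <- select_de_signature(rec, p_threshold = p_threshold, top_k = top_k)
  rec$selected <- rec$protein_id %in% sig
  rec <- rec[order(rec$p_long_vs_normal), ]
  rownames(rec) <- NULL
  attr(rec, "signature") <- sig
  rec
}

#' Select the direction-consistent top-k differential signature
#'
#' Filters to proteins differentially expressed between long-term and normal
#' responders (pairwise p below `p_threshold`) whose long-vs-normal and
#' long-vs-poor fold changes share a nonzero sign, ranks them by ascending
#' p-value, and returns the first `top_k` (fewer if fewer qualify). Ties at
#' the boundary are broken by larger absolute long-vs-normal fold change,
#' then lexicographic protein id, so the output is deterministic.
#'
#' @param records output of [differential_expression()] (or any data.frame
#'   with the same columns).
#' @param p_threshold pairwise p-value cutoff (default 0.1).
#' @param top_k maximum signature size (default 15).
#' @return Ordered character vector of protein ids.
#' @export
select_de_signature <- function(records, p_threshold = 0.1, top_k = 15) {
  eligible <- !is.na(records$p_long_vs_normal) &
    records$p_long_vs_normal < p_threshold &
    !is.na(records$fc_long_vs_normal) & !is.na(records$fc_long_vs_poor) &
    records$fc_long_vs_normal != 0 & records$fc_long_vs_poor != 0 &
    sign(records$fc_long_vs_normal) == sign(records$fc_long_vs_poor)
  el <- records[eligible, , drop = FALSE]
  if (!nrow(el)) return(character(0))
  ord <- order(el$p_long_vs_normal, -abs(el$fc_long_vs_normal), el$protein_id)
  utils::head(el$protein_id[ord], top_k)
}
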