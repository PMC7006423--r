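#' Enumerate all protein panels up to a maximum size
#'
#' All subsets of 1..`max_size` candidates, each sorted lexicographically,
#' in deterministic order (by size, then lexicographic). 52 candidates at
#' `max_size = 3` give C(52,1)+C(52,2)+C(52,3) = 23,478 panels.
#'
#' @param candidates character vector of protein ids.
#' @param max_size maximum panel size (default 3).
#' @return list of character vectors.
#' @export
enumerate_panels <- function(candidates, max_size = 3L) {
  stopifnot(length(candidates) >= 1L, max_size >= 1L)
  candidates <- sort(unique(candidates))
  out <- list()
  for (k in seq_len(min(max_size, length(candidates)))) {
    cmb <- utils::combn(candidates, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted one half.
#'
#' @param scores numeric predictions.
#' @param labels binary (0/1 or logical) true classes.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC operating points of a score vector: (specificity, sensitivity) at
# every threshold "score >= t is called positive", plus the two endpoints.
roc_points <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0L] < t), numeric(1))
  data.frame(specificity = c(1, spec, 0), sensitivity = c(0, sens, 1))
}

#' Vertically average ROC curves on a fixed specificity grid
#'
#' Each per-trial curve is step-interpolated (the best sensitivity
#' achievable at or above a given specificity) and sensitivities are
#' averaged pointwise across trials.
#'
#' @param curves list of data.frames with `specificity`, `sensitivity`.
#' @param grid specificity grid (default 0, 0.01, ..., 1).
#' @return data.frame with `specificity`, `sensitivity` (mean over trials).
#' @export
average_roc <- function(curves, grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(curves) >= 1L)
  sens <- vapply(curves, function(cv) {
    vapply(grid, function(g) {
      ok <- cv$specificity >= g - 1e-12
      if (any(ok)) max(cv$sensitivity[ok]) else 0
    }, numeric(1))
  }, numeric(length(grid)))
  data.frame(specificity = grid, sensitivity = rowMeans(as.matrix(sens)))
}

#' Optimism-corrected cross-validated AUC of a protein panel
#'
#' For each of `n_cv` stratified half-splits, a Firth bias-reduced logistic
#' model is fit on the training half and scored on the held-out half. The
#' split's null AUC is the median out-of-sample AUC over `n_shuffles`
#' refits with permuted training labels; its excess over the theoretical
#' 0.5 (the "optimism") is subtracted from the split's observed AUC. The
#' panel estimate is the median corrected AUC over splits, with a 2.5-97.5%
#' quantile interval, plus the vertically averaged ROC curve.
#'
#' @param panel character vector of 1-3 protein ids.
#' @param matrix complete [expression_matrix()] (impute and z-score first).
#' @param labels binary vector aligned with the matrix rows.
#' @param n_cv number of half-splits (default 100).
#' @param n_shuffles label shuffles per split (default 50).
#' @param seed integer; panel results are invariant to protein order given
#'   the same seed.
#' @param keep_roc keep the averaged ROC curve (default TRUE).
#' @return A `"panel_record"` list: `proteins`, `cv_aucs`, `null_aucs`
#'   (per-split null medians), `corrected_aucs`, `corrected_auc_median`,
#'   `ci_low`, `ci_high`, `avg_roc`.
#' @export
optimism_corrected_auc <- function(panel, matrix, labels, n_cv = 100L,
                                   n_shuffles = 50L, seed = 1L,
                                   keep_roc = TRUE) {
  panel <- sort(unique(panel))
  stopifnot(length(panel) >= 1L)
  missing_ids <- setdiff(panel, colnames(matrix))
  if (length(missing_ids))
    stop("panel proteins absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  if (anyNA(matrix)) stop("matrix must be complete; impute first")
  y <- as.integer(as.logical(labels))
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("both classes need at least 2 members")
  X <- unclass(matrix)[, panel, drop = FALSE]

  cv_aucs <- null_meds <- corrected <- numeric(n_cv)
  rocs <- if (keep_roc) vector("list", n_cv) else NULL
  for (s in seq_len(n_cv)) {
    split_seed <- derive_seed(seed, paste0("panel_", paste(panel, collapse = "|")), s)
    with_seed(split_seed, {
      repeat {
        tr <- stratified_half_split(y, parity = s)
        if (length(unique(y[tr])) == 2L && length(unique(y[!tr])) == 2L) break
      }
      xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
      fit <- firth_glm(xtr, ytr)
      sc <- predict(fit, xte, type = "link")
      cv_aucs[s] <- auc(sc, yte)
      nulls <- vapply(seq_len(n_shuffles), function(b) {
        repeat {
          ysh <- sample(ytr)
          if (length(unique(ysh)) == 2L) break
        }
        nf <- firth_glm(xtr, ysh)
        auc(predict(nf, xte, type = "link"), yte)
      }, numeric(1))
      null_meds[s] <- stats::median(nulls)
      corrected[s] <- cv_aucs[s] - (null_meds[s] - 0.5)
      if (keep_roc) rocs[[s]] <- roc_points(sc, yte)
    })
  }
  qs <- stats::quantile(corrected, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(proteins = panel,
                 cv_aucs = cv_aucs, null_aucs = null_meds,
                 corrected_aucs = corrected,
                 corrected_auc_median = stats::median(corrected),
                 ci_low = qs[1L], ci_high = qs[2L],
                 avg_roc = if (keep_roc) average_roc(rocs) else NULL),
            class = "panel_record")
}

#' @method print panel_record
#' @export
print.panel_record <- function(x, ...) {
  cat(sprintf("<panel_record> {%s}: corrected AUC %.3f [%.3f, %.3f]\n",
              paste(x$proteins, collapse = ", "),
              x$corrected_auc_median, x$ci_low, x$ci_high))
  invisible(x)
}

#' Evaluate a list of panels
#'
#' Runs [optimism_corrected_auc()] for every panel with per-panel seeds
#' derived from `seed` (results independent of evaluation order) and
#' returns the records with a one-row-per-panel summary.
#'
#' @inheritParams optimism_corrected_auc
#' @param panels list of protein-id vectors (see [enumerate_panels()]).
#' @param max_panels optional cap; the first `max_panels` panels in
#'   enumeration order are evaluated.
#' @return list with `records` and `summary` (data.frame: panel, size,
#'   corrected_auc_median, ci_low, ci_high).
#' @export
evaluate_panels <- function(panels, matrix, labels, n_cv = 100L,
                            n_shuffles = 50L, seed = 1L,
                            max_panels = Inf, keep_roc = FALSE) {
  if (is.finite(max_panels) && length(panels) > max_panels)
    panels <- panels[seq_len(max_panels)]
  records <- lapply(seq_along(panels), function(i) {
    optimism_corrected_auc(panels[[i]], matrix, labels, n_cv = n_cv,
                           n_shuffles = n_shuffles,
                           seed = derive_seed(seed, "panel", i),
                           keep_roc = keep_roc)
  })
  summary <- data.frame(
    panel = vapply(records, function(r) paste(r$proteins, collapse = "+"),
                   character(1)),
    size = vapply(records, function(r) length(r$proteins), integer(1)),
    corrected_auc_median = vapply(records, `[[`, numeric(1),
                                  "corrected_auc_median"),
    ci_low = vapply(records, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(records, `[[`, numeric(1), "ci_high"),
    stringsAsFactors = FALSE)
  list(records = records, summary = summary)
}

#' Protein contributions to high-performance panels
#'
#' Among panels whose optimism-corrected median AUC exceeds
#' `auc_threshold`, computes for each protein the proportion of such panels
#' containing it; proteins above `min_proportion` form the contributing
#' set.
#'
#' @param records list of `panel_record` objects.
#' @param auc_threshold high-performance cutoff (default 0.85).
#' @param min_proportion contribution cutoff (default 0.05).
#' @return list with `table` (data.frame: protein_id, proportion,
#'   n_high_panels), `contributing` (character), `n_high` (count of high
#'   panels).
#' @export
contribution_analysis <- function(records, auc_threshold = 0.85,
                                  min_proportion = 0.05) {
  high <- Filter(function(r) r$corrected_auc_median > auc_threshold, records)
  if (!length(high)) {
    warning("no panel exceeds the AUC threshold")
    return(list(table = data.frame(protein_id = character(0),
                                   proportion = numeric(0),
                                   n_high_panels = integer(0)),
                contributing = character(0), n_high = 0L))
  }
  members <- unlist(lapply(high, `[[`, "proteins"))
  counts <- table(members)
  tab <- data.frame(protein_id = names(counts),
                    proportion = as.numeric(counts) / length(high),
                    n_high_panels = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$proportion, tab$protein_id), ]
  rownames(tab) <- NULL
  list(table = tab,
       contributing = sort(tab$protein_id[tab$proportion > min_proportion]),
       n_high = length(high))
}

#' Intersect the analysis lists into a final signature
#'
#' Combines the differential-expression signature with the two
#' panel-contribution lists (long-vs-normal and long-vs-poor). Reports the
#' full Venn membership pattern; the default rule keeps every protein named
#' by at least one analysis (annotated by pattern), the strict rule keeps
#' proteins named by at least two. Proteins present in all three lists are
#' flagged as top candidates.
#'
#' @param de_list,contrib_lvn,contrib_lvp character vectors of protein ids.
#' @param rule `"union"` (default) or `"strict"` (>= 2 lists).
#' @return list with `final` (character), `top_candidates` (in all three
#'   lists), `membership` (data.frame with logical columns per list and
#'   `n_lists`), `venn` (named counts of the 7 regions).
#' @export
final_signature <- function(de_list, contrib_lvn, contrib_lvp,
                            rule = c("union", "strict")) {
  rule <- match.arg(rule)
  all_ids <- sort(unique(c(de_list, contrib_lvn, contrib_lvp)))
  mem <- data.frame(protein_id = all_ids,
                    de = all_ids %in% de_list,
                    contrib_long_vs_normal = all_ids %in% contrib_lvn,
                    contrib_long_vs_poor = all_ids %in% contrib_lvp,
                    stringsAsFactors = FALSE)
  mem$n_lists <- mem$de + mem$contrib_long_vs_normal + mem$contrib_long_vs_poor
  pattern <- paste0(ifelse(mem$de, "D", ""),
                    ifelse(mem$contrib_long_vs_normal, "N", ""),
                    ifelse(mem$contrib_long_vs_poor, "P", ""))
  venn <- vapply(c("D", "N", "P", "DN", "DP", "NP", "DNP"),
                 function(pt) sum(pattern == pt), integer(1))
  final <- if (rule == "union") mem$protein_id
           else mem$protein_id[mem$n_lists >= 2L]
  list(final = final,
       top_candidates = mem$protein_id[mem$n_lists == 3L],
       membership = mem, venn = venn, rule = rule)
}
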