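#' Single-sample enrichment scores for a protein signature
#'
#' Per-sample ssGSEA statistic: proteins are ranked by expression within the
#' sample (descending); the enrichment score is the sum, over the ordered
#' protein list, of the difference between the weighted cumulative
#' distribution of in-signature proteins (weights = rank value^alpha,
#' normalized to sum to one) and the uniform cumulative distribution of
#' out-of-signature proteins. Depends only on within-sample ranks, so it is
#' invariant to any monotone transformation of a sample's values.
#'
#' @param matrix [expression_matrix()] with no missing values (impute
#'   first, see [impute_missing()]).
#' @param signature character vector of protein ids; must be a non-empty
#'   proper subset of the matrix proteins.
#' @param alpha rank-weight exponent (default 0.25, the canonical ssGSEA
#'   weighting).
#' @param normalize_ranks divide rank values by the protein count before
#'   exponentiation (default `TRUE`; the enrichment score is unchanged
#'   because weights are renormalized, the flag only affects reported
#'   weights).
#' @return data.frame with `patient_id`, `enrichment_score`, `rank`
#'   (1 = highest score).
#' @export
ssgsea_score <- function(matrix, signature, alpha = 0.25,
                         normalize_ranks = TRUE) {
  stopifnot(inherits(matrix, "expr_matrix"), alpha >= 0)
  if (!length(signature)) stop("signature is empty")
  missing_ids <- setdiff(signature, colnames(matrix))
  if (length(missing_ids))
    stop("signature proteins absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  if (anyDuplicated(signature)) stop("duplicate proteins in signature")
  n <- ncol(matrix)
  if (length(signature) >= n)
    stop("signature must be a proper subset of the matrix proteins ",
         "(the out-of-signature distribution is undefined otherwise)")
  if (anyNA(matrix))
    stop("matrix contains missing values; impute before scoring")
  in_sig <- colnames(matrix) %in% signature
  es <- vapply(seq_len(nrow(matrix)), function(i) {
    x <- unclass(matrix)[i, ]
    ord <- order(-x, colnames(matrix))  # descending, ties by id
    hit <- in_sig[ord]
    rank_val <- n - seq_len(n) + 1
    if (normalize_ranks) rank_val <- rank_val / n
    w <- rank_val^alpha
    p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    p_out <- cumsum(!hit) / (n - sum(in_sig))
    sum(p_in - p_out)
  }, numeric(1))
  out <- data.frame(patient_id = rownames(matrix), enrichment_score = es,
                    stringsAsFactors = FALSE)
  ord <- order(-out$enrichment_score, out$patient_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Rank patients by enrichment score
#'
#' Sorts patients by descending score (ties broken by patient id), annotates
#' response groups, and summarizes the per-group mean score and how many
#' long-term responders occupy the top positions.
#'
#' @param scores output of [ssgsea_score()].
#' @param cohort grouped cohort.
#' @return A list: `ranking` (data.frame sorted by descending score),
#'   `group_means` (named numeric), and `top_capture` (number of long-term
#'   responders among the first n_long ranks).
#' @export
rank_patients <- function(scores, cohort) {
  m <- merge(scores, cohort[, c("patient_id", "group")], by = "patient_id")
  m <- m[order(-m$enrichment_score, m$patient_id), ]
  rownames(m) <- NULL
  gm <- tapply(m$enrichment_score, m$group, mean)
  n_long <- sum(m$group == "long_term", na.rm = TRUE)
  capture <- if (n_long > 0)
    sum(m$group[seq_len(n_long)] == "long_term", na.rm = TRUE) else 0L
  list(ranking = m, group_means = gm, top_capture = capture)
}
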