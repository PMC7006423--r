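# small in-code fixtures shared across test files

toy_matrix <- function(vals, samples = NULL, proteins = NULL) {
  n <- nrow(vals)
  p <- ncol(vals)
  expression_matrix(vals,
                    sample_ids = samples %||% sprintf("S%02d", seq_len(n)),
                    protein_ids = proteins %||% sprintf("PR%02d", seq_len(p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_cohort <- function(pfs, ids = sprintf("S%02d", seq_along(pfs)),
                       progressed = rep(TRUE, length(pfs))) {
  assign_response_groups(data.frame(patient_id = ids, pfs_months = pfs,
                                    progressed = progressed,
                                    stringsAsFactors = FALSE))
}

# a 22-sample cohort matching the study layout: 5 poor, 10 normal, 7 long
study_like_cohort <- function() {
  toy_cohort(c(runif(5, 0.6, 2.9), runif(10, 4, 22), runif(7, 25, 40)))
}

# independent penalized log-likelihood for the Firth oracle (written from
# the definition, no package code)
oracle_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pii <- 1 / (1 + exp(-eta))
  w <- pii * (1 - pii)
  info <- t(X * w) %*% X
  d <- det(info)
  if (d <= 0) return(-Inf)
  sum(y * eta - log(1 + exp(eta))) + 0.5 * log(d)
}

# iterated 2-D grid search maximizing the penalized likelihood for a model
# with intercept + one covariate
oracle_firth_grid <- function(x, y, half_width = 8, n_grid = 33L,
                              n_refine = 6L) {
  X <- cbind(1, x)
  c0 <- c(0, 0)
  hw <- half_width
  for (r in seq_len(n_refine)) {
    g1 <- seq(c0[1] - hw, c0[1] + hw, length.out = n_grid)
    g2 <- seq(c0[2] - hw, c0[2] + hw, length.out = n_grid)
    grid <- as.matrix(expand.grid(g1, g2))
    vals <- apply(grid, 1L, function(b) oracle_pll(X, y, b))
    c0 <- grid[which.max(vals), ]
    hw <- hw * 2.5 / (n_grid - 1)   # keep the new box around the best cell
  }
  c0
}

# brute-force step-up false-discovery-rate adjustment, straight from the
# definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- pmin(1, m * p[o] / seq_len(m))
  q[o] <- rev(cummin(rev(adj)))
  q
}

# pair-counting AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
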