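learner_kinds <- c("gbdt", "lasso", "ridge", "elastic_net")

# stratified fold ids for the inner penalty-selection CV
stratified_foldid <- function(y, nfolds = 3L) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    id[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  id
}

fit_penalized_importance <- function(xtr, ytr, alpha) {
  foldid <- stratified_foldid(ytr, 3L)
  # a 30-point lambda path is ample at these sample sizes and keeps the
  # 10,000-trial ensemble tractable
  cv <- suppressWarnings(
    glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = alpha,
                      foldid = foldid, standardize = FALSE,
                      grouped = FALSE, nlambda = 30L))
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  beta^2
}

fit_gbdt_importance <- function(xtr, ytr, params, trial_seed) {
  dtr <- xgboost::xgb.DMatrix(xtr, label = ytr)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth, eta = params$eta,
                  min_child_weight = params$min_child_weight %||% 0,
                  nthread = 1L, seed = trial_seed),
    data = dtr, nrounds = params$nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  out <- stats::setNames(numeric(ncol(xtr)), colnames(xtr))
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

#' Repeated cross-validated feature-importance trials
#'
#' For each of `n_orders` random permutations of protein-column order and
#' each of `n_cv` stratified half-splits, fits each learner on the training
#' half and records per-protein importance: total split gain for
#' gradient-boosted trees, squared fitted coefficient for the penalized
#' regressions (lasso, ridge, elastic net with mixing 0.5; penalty chosen by
#' an inner stratified 3-fold CV on the training half). Importances are
#' averaged over all trials. Column-order randomization matters only for the
#' tree learner, whose split tie-breaks depend on column order; averaging
#' over orders removes that artifact.
#'
#' @param matrix complete (imputed), z-scored [expression_matrix()].
#' @param labels binary vector (0/1) aligned with the matrix rows.
#' @param learners subset of `c("gbdt", "lasso", "ridge", "elastic_net")`.
#' @param n_orders,n_cv numbers of column orders and of half-splits per
#'   order (the reference analysis uses 100 x 100 = 10,000 trials).
#' @param seed integer; every split, permutation and learner seed derives
#'   from it.
#' @param gbdt_params list with `nrounds`, `max_depth`, `eta`.
#' @return data.frame (long format): `protein_id`, `learner`,
#'   `mean_importance`, `n_trials`.
#' @export
run_importance_trials <- function(matrix, labels,
                                  learners = learner_kinds,
                                  n_orders = 100L, n_cv = 100L, seed = 1L,
                                  gbdt_params = list(nrounds = 100L,
                                                     max_depth = 3L,
                                                     eta = 0.3,
                                                     min_child_weight = 0)) {
  stopifnot(all(learners %in% learner_kinds))
  if (anyNA(matrix)) stop("matrix must be complete; impute first")
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(matrix), all(y %in% 0:1))
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("both classes need at least 2 members")
  X <- unclass(matrix)
  p <- ncol(X)
  alphas <- c(lasso = 1, ridge = 0, elastic_net = 0.5)
  sums <- matrix(0, p, length(learners),
                 dimnames = list(colnames(X), learners))
  counts <- stats::setNames(integer(length(learners)), learners)

  trial <- 0L
  for (o in seq_len(n_orders)) {
    perm <- with_seed(derive_seed(seed, "order", o), sample.int(p))
    Xp <- X[, perm, drop = FALSE]
    for (cv in seq_len(n_cv)) {
      trial <- trial + 1L
      tr <- with_seed(derive_seed(seed, "split", trial),
                      stratified_half_split(y, parity = trial))
      xtr <- Xp[tr, , drop = FALSE]; ytr <- y[tr]
      for (ln in learners) {
        imp <- tryCatch(
          with_seed(derive_seed(seed, paste0("fit_", ln), trial), {
            if (ln == "gbdt")
              fit_gbdt_importance(xtr, ytr, gbdt_params,
                                  derive_seed(seed, "xgb", trial))
            else fit_penalized_importance(xtr, ytr, alphas[[ln]])
          }),
          error = function(e) NULL)
        if (is.null(imp)) next
        # column j of the permuted design is original protein perm[j]
        sums[perm, ln] <- sums[perm, ln] + as.numeric(imp)
        counts[ln] <- counts[ln] + 1L
      }
    }
  }
  out <- do.call(rbind, lapply(learners, function(ln) {
    data.frame(protein_id = colnames(X), learner = ln,
               mean_importance = if (counts[ln] > 0)
                 sums[, ln] / counts[ln] else NA_real_,
               n_trials = counts[ln], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# profile log-likelihood of the two-piece exponential over all candidate
# breakpoints; x sorted ascending. Within any inter-event interval the
# likelihood is monotone in the breakpoint (it moves exposure between the
# two hazard pieces), so the profile optimum sits at an observed value:
# candidates are the distinct values, each closing its own piece.
two_piece_profile <- function(x) {
  m <- length(x)
  xs <- sort(x)
  S <- cumsum(xs)
  total <- S[m]
  k <- which(diff(xs) > 0)            # break after position k
  if (!length(k)) return(NULL)
  cand <- xs[k]
  T1 <- S[k] + (m - k) * cand
  T2 <- (total - S[k]) - (m - k) * cand
  ok <- T1 > 0 & T2 > 0
  if (!any(ok)) return(NULL)
  k <- k[ok]; cand <- cand[ok]; T1 <- T1[ok]; T2 <- T2[ok]
  d1 <- k; d2 <- m - k
  # a selection-relevant rate change is a decay that slows at the break (a
  # persistent high-importance tail): require hazard2 < hazard1
  drop_rate <- d2 / T2 < d1 / T1
  if (!any(drop_rate)) return(NULL)
  k <- k[drop_rate]; cand <- cand[drop_rate]
  T1 <- T1[drop_rate]; T2 <- T2[drop_rate]
  d1 <- d1[drop_rate]; d2 <- d2[drop_rate]
  ll2 <- d1 * log(d1 / T1) - d1 + d2 * log(d2 / T2) - d2
  ll1 <- if (total > 0) m * log(m / total) - m else -Inf
  best <- which.max(ll2)
  list(threshold = cand[best], lrt = 2 * (ll2[best] - ll1),
       loglik2 = ll2[best], loglik1 = ll1)
}

# gamma MLE on positive values (Newton on the shape equation, method-of-
# moments style closed-form start); returns c(shape, rate)
gamma_mle_pos <- function(x) {
  mx <- mean(x)
  s <- log(mx) - mean(log(x))
  if (!is.finite(s) || s <= 0) return(c(1, 1 / mx))
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
    shape_new <- shape - step
    if (!is.finite(shape_new) || shape_new <= 0) break
    conv <- abs(shape_new - shape) < 1e-10
    shape <- shape_new
    if (conv) break
  }
  c(shape, shape / mx)
}

#' Survivor-function rate-change importance cutoff
#'
#' Detects a change in the decay rate of the survivor function of
#' per-protein importance values by fitting a two-piece exponential
#' (piecewise-constant hazard on the importance axis) by maximum likelihood
#' over all candidate breakpoints. The one-piece null is taken as a gamma
#' distribution (which generalizes the exponential, shape 1): importances
#' are probability-integral transformed through the fitted gamma, so that
#' under the null the transformed values are unit-exponential and the
#' two-piece changepoint model is well specified; smooth departures from
#' exponential decay are absorbed by the gamma baseline rather than read as
#' rate changes. Significance is assessed with a seeded parametric
#' bootstrap from the fitted gamma (the unknown-breakpoint likelihood-ratio
#' statistic has no standard chi-square null), and the detected breakpoint
#' is mapped back through the gamma quantiles. If the test rejects at
#' `level`,
#' proteins with importance strictly above the breakpoint are selected;
#' otherwise the selection is empty. Exact zeros (proteins never used by
#' the learner) are never selectable and are excluded from the fit. A
#' model-free alternative (`method = "second_diff"`) places the cutoff at
#' the maximum second difference of the log-survivor curve.
#'
#' @param importances named nonnegative numeric vector (one learner's mean
#'   importances); needs at least 3 distinct positive values.
#' @param level test level (default 0.05).
#' @param n_boot bootstrap replicates for the null distribution.
#' @param seed integer seed for the bootstrap.
#' @param method `"lrt_boot"` (default) or `"second_diff"`.
#' @return list with `threshold` (`NA` when nothing is selected),
#'   `selected` (character), `p_value` (bootstrap, `NA` for the heuristic),
#'   `stat` (the bootstrap test statistic).
#' @export
survivor_rate_change_cutoff <- function(importances, level = 0.05,
                                        n_boot = 199L, seed = 1L,
                                        method = c("lrt_boot",
                                                   "second_diff")) {
  method <- match.arg(method)
  imp <- importances
  if (is.null(names(imp))) names(imp) <- seq_along(imp)
  stopifnot(all(imp >= 0, na.rm = TRUE))
  imp <- imp[!is.na(imp)]
  if (all(imp == 0)) {
    warning("all importances are zero; empty selection")
    return(list(threshold = NA_real_, selected = character(0),
                p_value = NA_real_, stat = NA_real_))
  }
  if (length(unique(imp[imp > 0])) < 3L)
    stop("need at least 3 distinct positive importance values")

  if (method == "second_diff") {
    # empirical hazard on each inter-value interval = slope of the
    # log-survivor curve per unit importance; the cutoff sits where the
    # hazard drops the most (log ratio of consecutive slopes)
    v <- sort(unique(imp))
    m <- length(imp)
    surv <- vapply(v, function(t) sum(imp > t) / m, numeric(1))
    v <- v[surv > 0]; ls <- log(surv[surv > 0])
    if (length(ls) < 3L) stop("log-survivor curve too short")
    haz <- -diff(ls) / diff(v)
    j <- which.max(utils::head(haz, -1L) / utils::tail(haz, -1L))
    thr <- v[j + 1L]
    return(list(threshold = thr, selected = names(imp)[imp > thr],
                p_value = NA_real_, stat = NA_real_))
  }

  pos <- imp[imp > 0]
  m <- length(pos)
  gam <- gamma_mle_pos(pos)
  # gamma probability-integral transform: under the fitted one-piece gamma
  # null the transformed values are unit-exponential, so the two-piece
  # exponential changepoint fit is well specified on the transformed scale;
  # the detected breakpoint maps back through the gamma quantiles
  stat_of <- function(x) {
    g <- gamma_mle_pos(x)
    u <- stats::qexp(pmin(stats::pgamma(x, g[1], g[2]), 1 - 1e-12))
    pr <- two_piece_profile(u)
    if (is.null(pr)) return(list(stat = 0, threshold = NA_real_))
    list(stat = pr$lrt,
         threshold = stats::qgamma(stats::pexp(pr$threshold), g[1], g[2]))
  }
  obs <- stat_of(pos)
  if (!is.finite(obs$stat) || is.na(obs$threshold))
    return(list(threshold = NA_real_, selected = character(0),
                p_value = NA_real_, stat = NA_real_))
  boot <- with_seed(derive_seed(seed, "ratechange"), {
    vapply(seq_len(n_boot), function(b) {
      stat_of(stats::rgamma(m, gam[1], gam[2]))$stat
    }, numeric(1))
  })
  p <- (1 + sum(boot >= obs$stat)) / (n_boot + 1)
  if (p <= level) {
    list(threshold = obs$threshold,
         selected = names(imp)[imp > obs$threshold],
         p_value = p, stat = obs$stat)
  } else {
    list(threshold = NA_real_, selected = character(0),
         p_value = p, stat = obs$stat)
  }
}

#' Ensemble candidate selection over learners and contrasts
#'
#' Runs [run_importance_trials()] followed by
#' [survivor_rate_change_cutoff()] for each learner and each pairwise
#' classification (long-term vs normal, long-term vs poor by default), and
#' combines candidates as the union over learners and contrasts — a protein
#' is a panel-search candidate if at least one learner selected it in either
#' classification.
#'
#' @param matrix detected-protein [expression_matrix()]; imputed (median)
#'   and z-scored internally if needed.
#' @param cohort grouped cohort.
#' @param learners learner subset.
#' @param contrasts list of 2-vectors of group names; the first group is
#'   coded 1.
#' @param n_orders,n_cv,seed,gbdt_params passed to
#'   [run_importance_trials()].
#' @param level,cutoff_method,n_boot passed to
#'   [survivor_rate_change_cutoff()].
#' @return list with per-contrast results (importance table, per-learner
#'   thresholds and selections, union), and `combined` — the overall
#'   candidate set, sorted.
#' @export
select_candidates <- function(matrix, cohort, learners = learner_kinds,
                              contrasts = list(c("long_term", "normal"),
                                               c("long_term", "poor")),
                              n_orders = 100L, n_cv = 100L, seed = 1L,
                              gbdt_params = list(nrounds = 100L,
                                                 max_depth = 3L, eta = 0.3,
                                                 min_child_weight = 0),
                              level = 0.05,
                              cutoff_method = "lrt_boot", n_boot = 199L) {
  if (anyNA(matrix)) matrix <- impute_missing(matrix, "median")
  matrix <- zscore_normalize(matrix)
  al <- align_groups(matrix, cohort)
  res <- list()
  for (ci in seq_along(contrasts)) {
    pair <- contrasts[[ci]]
    name <- paste(pair, collapse = "_vs_")
    in_pair <- al$groups %in% pair
    sub <- al$matrix[in_pair, , drop = FALSE]
    y <- as.integer(al$groups[in_pair] == pair[1L])
    imp <- run_importance_trials(sub, y, learners = learners,
                                 n_orders = n_orders, n_cv = n_cv,
                                 seed = derive_seed(seed, name),
                                 gbdt_params = gbdt_params)
    per_learner <- lapply(learners, function(ln) {
      v <- imp$mean_importance[imp$learner == ln]
      names(v) <- imp$protein_id[imp$learner == ln]
      if (length(unique(v[!is.na(v) & v > 0])) < 3L) {
        # a learner that attributed (almost) no importance selects nothing
        return(list(threshold = NA_real_, selected = character(0),
                    p_value = NA_real_, stat = NA_real_))
      }
      survivor_rate_change_cutoff(v, level = level, n_boot = n_boot,
                                  seed = derive_seed(seed, paste0(name, "_", ln)),
                                  method = cutoff_method)
    })
    names(per_learner) <- learners
    union_sel <- sort(unique(unlist(lapply(per_learner, `[[`, "selected"))))
    res[[name]] <- list(contrast = pair, importance = imp,
                        cutoffs = per_learner, union_selected = union_sel)
  }
  combined <- sort(unique(unlist(lapply(res, `[[`, "union_selected"))))
  c(res, list(combined = combined))
}
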