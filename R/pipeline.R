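#' Control parameters for signature discovery
#'
#' Collects every tunable of the end-to-end analysis with the reference
#' configuration as defaults: detection completeness 0.8 with median
#' imputation, inclusive 24-month long-term boundary, Welch pairwise test
#' with p < 0.1 and a top-15 direction-consistent signature, ssGSEA
#' exponent 0.25, four-learner ensemble, panel size up to 3 with 100
#' half-splits, 50 null shuffles, AUC threshold 0.85 and 5% contribution
#' cutoff.
#'
#' @param thresholds [group_thresholds()].
#' @param min_fraction detection filter completeness.
#' @param imputation `"median"`, `"half_minimum"` or `"none"`.
#' @param de_test,p_threshold,top_k differential-expression settings.
#' @param alpha ssGSEA rank-weight exponent.
#' @param learners,n_orders,n_cv_ensemble,gbdt_params,cutoff_level,cutoff_method,n_boot
#'   importance-ensemble settings.
#' @param max_size,n_cv_panels,n_shuffles,auc_threshold,min_proportion,max_panels
#'   panel-search settings.
#' @param signature_rule `"union"` or `"strict"` final combination rule.
#' @return list of class `"sig_control"`.
#' @export
sig_control <- function(thresholds = group_thresholds(),
                        min_fraction = 0.8, imputation = "median",
                        de_test = "welch_t", p_threshold = 0.1, top_k = 15,
                        alpha = 0.25,
                        learners = learner_kinds,
                        n_orders = 100L, n_cv_ensemble = 100L,
                        gbdt_params = list(nrounds = 100L, max_depth = 3L,
                                           eta = 0.3,
                                           min_child_weight = 0),
                        cutoff_level = 0.05, cutoff_method = "lrt_boot",
                        n_boot = 199L,
                        max_size = 3L, n_cv_panels = 100L, n_shuffles = 50L,
                        auc_threshold = 0.85, min_proportion = 0.05,
                        max_panels = Inf,
                        signature_rule = "union") {
  if (!all(learners %in% learner_kinds))
    stop("unknown learner(s): ",
         paste(setdiff(learners, learner_kinds), collapse = ", "))
  stopifnot(inherits(thresholds, "group_thresholds"),
            min_fraction > 0, min_fraction <= 1,
            p_threshold > 0, p_threshold <= 1, top_k >= 1, alpha >= 0,
            max_size >= 1, auc_threshold > 0, auc_threshold < 1,
            min_proportion >= 0, min_proportion < 1)
  imputation <- match.arg(imputation, c("median", "half_minimum", "none"))
  de_test <- match.arg(de_test, c("welch_t", "student_t", "mann_whitney"))
  signature_rule <- match.arg(signature_rule, c("union", "strict"))
  structure(as.list(environment()), class = "sig_control")
}

#' Discover a prognostic protein signature
#'
#' End-to-end signature discovery on a samples x proteins matrix of
#' normalized log2 L/H abundance ratios and a PFS-annotated cohort:
#' detection filtering and imputation, response-group assignment,
#' differential expression with the direction-consistent top-k rule, ssGSEA
#' patient scoring, four-learner importance-ensemble candidate selection,
#' exhaustive 1-3 protein panel search with optimism-corrected AUC,
#' contribution analysis per contrast, and the final multi-list signature.
#' Identical inputs, control and seed give identical results.
#'
#' @param matrix [expression_matrix()] (raw, may contain missing values).
#' @param cohort data.frame with `patient_id`, `pfs_months`, `progressed`.
#' @param control [sig_control()].
#' @param seed master seed; all stage seeds derive from it.
#' @return Object of class `"sig_discovery"`; see [summary.sig_discovery()].
#' @export
discover_signature <- function(matrix, cohort, control = sig_control(),
                               seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(control, "sig_control"))
  if (!"group" %in% names(cohort))
    cohort <- assign_response_groups(cohort, control$thresholds)

  detected <- filter_detected(matrix, control$min_fraction)
  complete <- impute_missing(detected, control$imputation)

  de <- differential_expression(detected, cohort, test = control$de_test,
                                p_threshold = control$p_threshold,
                                top_k = control$top_k)
  de_sig <- attr(de, "signature")

  scores <- if (length(de_sig))
    ssgsea_score(complete, de_sig, alpha = control$alpha) else NULL
  ranking <- if (!is.null(scores)) rank_patients(scores, cohort) else NULL

  sel <- select_candidates(complete, cohort, learners = control$learners,
                           n_orders = control$n_orders,
                           n_cv = control$n_cv_ensemble,
                           seed = derive_seed(seed, "ensemble"),
                           gbdt_params = control$gbdt_params,
                           level = control$cutoff_level,
                           cutoff_method = control$cutoff_method,
                           n_boot = control$n_boot)
  candidates <- sel$combined

  zs <- zscore_normalize(complete)
  al <- align_groups(zs, cohort)
  contrasts <- list(long_term_vs_normal = c("long_term", "normal"),
                    long_term_vs_poor = c("long_term", "poor"))
  panel_results <- list()
  contrib <- list()
  for (nm in names(contrasts)) {
    pair <- contrasts[[nm]]
    if (!length(candidates)) {
      panel_results[[nm]] <- list(
        summary = data.frame(panel = character(0), size = integer(0),
                             corrected_auc_median = numeric(0),
                             ci_low = numeric(0), ci_high = numeric(0)),
        n_high = 0L,
        contribution = data.frame(protein_id = character(0),
                                  proportion = numeric(0),
                                  n_high_panels = integer(0)))
      contrib[[nm]] <- character(0)
      next
    }
    in_pair <- al$groups %in% pair
    sub <- al$matrix[in_pair, , drop = FALSE]
    y <- as.integer(al$groups[in_pair] == pair[1L])
    panels <- enumerate_panels(candidates, control$max_size)
    ev <- evaluate_panels(panels, sub, y, n_cv = control$n_cv_panels,
                          n_shuffles = control$n_shuffles,
                          seed = derive_seed(seed, paste0("panels_", nm)),
                          max_panels = control$max_panels)
    ca <- suppressWarnings(
      contribution_analysis(ev$records, control$auc_threshold,
                            control$min_proportion))
    panel_results[[nm]] <- list(summary = ev$summary,
                                n_high = ca$n_high,
                                contribution = ca$table)
    contrib[[nm]] <- ca$contributing
  }

  fin <- final_signature(de_sig,
                         contrib$long_term_vs_normal %||% character(0),
                         contrib$long_term_vs_poor %||% character(0),
                         rule = control$signature_rule)

  structure(list(control = control, seed = seed,
                 n_samples = nrow(matrix),
                 n_monitored = ncol(matrix), n_detected = ncol(detected),
                 group_sizes = table(cohort$group),
                 cohort = cohort,
                 differential = de, de_signature = de_sig,
                 scores = scores, ranking = ranking,
                 selection = sel, candidates = candidates,
                 panels = panel_results,
                 contributing = contrib,
                 final = fin),
            class = "sig_discovery")
}

#' @method print sig_discovery
#' @export
print.sig_discovery <- function(x, ...) {
  gs <- paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
              collapse = ", ")
  cat("Prognostic signature discovery\n")
  cat(sprintf("  %d samples (%s); %d/%d proteins detected\n",
              x$n_samples, gs, x$n_detected, x$n_monitored))
  cat(sprintf("  DE signature: %d proteins; ensemble candidates: %d\n",
              length(x$de_signature), length(x$candidates)))
  for (nm in names(x$panels))
    cat(sprintf("  %s: %d high-AUC panels, %d contributing proteins\n",
                nm, x$panels[[nm]]$n_high, length(x$contributing[[nm]])))
  cat(sprintf("  Final signature (%s rule): %d proteins; top tier: %s\n",
              x$final$rule, length(x$final$final),
              if (length(x$final$top_candidates))
                paste(x$final$top_candidates, collapse = ", ") else "none"))
  invisible(x)
}

#' Summarize a signature-discovery result
#'
#' @param object a `"sig_discovery"` object.
#' @param ... unused.
#' @return Named list of the stage-level outputs (group sizes, detected
#'   count, DE signature, patient ranking, candidate set, per-contrast
#'   high-panel counts and contribution lists, final signature with Venn
#'   counts).
#' @method summary sig_discovery
#' @export
summary.sig_discovery <- function(object, ...) {
  out <- list(
    group_sizes = as.list(object$group_sizes),
    n_monitored = object$n_monitored,
    n_detected = object$n_detected,
    median_pfs = stats::median(object$cohort$pfs_months, na.rm = TRUE),
    de_signature = object$de_signature,
    top_capture = object$ranking$top_capture %||% NA_integer_,
    score_group_means = as.list(object$ranking$group_means %||% numeric(0)),
    n_candidates = length(object$candidates),
    candidates = object$candidates,
    n_high_panels = lapply(object$panels, `[[`, "n_high"),
    contributing = object$contributing,
    final_signature = object$final$final,
    top_candidates = object$final$top_candidates,
    venn = as.list(object$final$venn),
    seed = object$seed)
  class(out) <- "summary.sig_discovery"
  out
}

#' @method print summary.sig_discovery
#' @export
print.summary.sig_discovery <- function(x, ...) {
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Plot method: patient enrichment-score ranking
#'
#' Bar plot of per-patient ssGSEA scores for the differential signature,
#' colored by response group, in rank order.
#'
#' @param x `"sig_discovery"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sig_discovery <- function(x, ...) {
  if (is.null(x$ranking)) stop("no enrichment scores in this result")
  r <- x$ranking$ranking
  cols <- c(poor = "#4477AA", normal = "#EE6677", long_term = "#228833")
  graphics::barplot(r$enrichment_score, names.arg = r$patient_id,
                    col = cols[as.character(r$group)], las = 2,
                    ylab = "ssGSEA enrichment score", ...)
  graphics::legend("topright", legend = names(cols), fill = cols, bty = "n")
  invisible(x)
}

#' Run the discovery pipeline and write its artifacts
#'
#' Convenience wrapper over [discover_signature()] that reads the inputs
#' from disk (or accepts in-memory objects), runs the full analysis, and
#' writes stage artifacts to an output directory: the differential table,
#' the selected signature, patient scores, the importance tables,
#' per-contrast panel summaries and contributions, and a consolidated
#' `report.json`.
#'
#' @param matrix path to an expression-matrix file or an
#'   [expression_matrix()].
#' @param cohort path to a cohort table or a data.frame.
#' @param out_dir output directory.
#' @param control [sig_control()].
#' @param seed master seed.
#' @return The `"sig_discovery"` object, invisibly.
#' @export
run_pipeline <- function(matrix, cohort, out_dir, control = sig_control(),
                         seed = 1L) {
  if (is.character(matrix)) matrix <- read_expression_matrix(matrix)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  fit <- discover_signature(matrix, cohort, control = control, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$differential, file.path(out_dir, "differential.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(fit$de_signature, file.path(out_dir, "de_signature.txt"))
  if (!is.null(fit$scores))
    utils::write.table(fit$scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(fit$selection)) {
    if (nm == "combined") next
    utils::write.table(fit$selection[[nm]]$importance,
                       file.path(out_dir, paste0("importance_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(fit$panels)) {
    utils::write.table(fit$panels[[nm]]$summary,
                       file.path(out_dir, paste0("panels_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fit$panels[[nm]]$contribution,
                       file.path(out_dir, paste0("contributions_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report <- summary(fit)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
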