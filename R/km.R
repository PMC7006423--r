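#' Kaplan-Meier median split on a single protein
#'
#' Splits patients at the median expression of one protein (ties go to the
#' low-expression arm), estimates progression-free survival per arm by the
#' Kaplan-Meier product-limit estimator, and tests the arms with a
#' two-sided log-rank test. Patients with unknown PFS are excluded;
#' progression observed is the event, progression-free patients are
#' censored at last follow-up.
#'
#' @param protein protein id present in `matrix`.
#' @param matrix [expression_matrix()].
#' @param cohort data.frame with `patient_id`, `pfs_months`, `progressed`.
#' @return A list: `curves` data.frame (`arm`, `time`, `survival`,
#'   `n_risk`, `n_event`), `logrank_p`, `median_expression`, and per-arm
#'   patient ids.
#' @export
km_median_split <- function(protein, matrix, cohort) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!protein %in% colnames(matrix))
    stop("protein not in matrix: ", protein)
  keep <- cohort$patient_id %in% rownames(matrix) & !is.na(cohort$pfs_months)
  co <- cohort[keep, , drop = FALSE]
  if (!nrow(co)) stop("no patients with known PFS in the matrix")
  expr <- unclass(matrix)[co$patient_id, protein]
  if (anyNA(expr)) {
    co <- co[!is.na(expr), , drop = FALSE]
    expr <- expr[!is.na(expr)]
  }
  med <- stats::median(expr)
  arm <- factor(ifelse(expr <= med, "low", "high"), levels = c("low", "high"))
  if (nlevels(droplevels(arm)) < 2L)
    stop("median split puts all patients in one arm for ", protein)
  ev <- if ("progressed" %in% names(co)) as.integer(co$progressed) else 1L
  ev[is.na(ev)] <- 1L
  surv <- survival::Surv(co$pfs_months, ev)
  fit <- survival::survfit(surv ~ arm)
  sd <- survival::survdiff(surv ~ arm)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  st <- summary(fit)
  curves <- data.frame(
    arm = sub("^arm=", "", as.character(st$strata)),
    time = st$time, survival = st$surv,
    n_risk = st$n.risk, n_event = st$n.event,
    stringsAsFactors = FALSE)
  list(curves = curves, logrank_p = p, median_expression = med,
       low = co$patient_id[arm == "low"], high = co$patient_id[arm == "high"])
}
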