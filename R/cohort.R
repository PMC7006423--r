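#' Response-group thresholds
#'
#' Duration-of-response stratification used throughout: poor responders
#' progress by `poor_max` months (default 3, i.e. at first radiologic
#' evaluation), long-term responders reach `long_min` months (default 24,
#' the typical ceiling of response duration to ALK TKIs), everyone else is a
#' normal responder. The 24-month boundary is inclusive by default
#' (`long_min_inclusive = TRUE`), matching the cohort definition that puts
#' n = 7 patients in the long-term group; the exclusive reading is available
#' because both appear in common usage.
#'
#' @param poor_max months; PFS <= `poor_max` is a poor responder.
#' @param long_min months; PFS >= `long_min` (or strictly greater when
#'   `long_min_inclusive = FALSE`) is a long-term responder.
#' @param long_min_inclusive logical.
#' @return A `"group_thresholds"` list.
#' @export
group_thresholds <- function(poor_max = 3, long_min = 24,
                             long_min_inclusive = TRUE) {
  stopifnot(poor_max > 0, long_min > poor_max)
  structure(list(poor_max = poor_max, long_min = long_min,
                 long_min_inclusive = isTRUE(long_min_inclusive)),
            class = "group_thresholds")
}

response_levels <- c("poor", "normal", "long_term")

#' Assign response groups from progression-free survival
#'
#' @param cohort data.frame with columns `patient_id`, `pfs_months` and
#'   optionally `progressed`. Unknown PFS (`NA`) yields an unknown group;
#'   such patients are excluded downstream.
#' @param thresholds a [group_thresholds()] object.
#' @return The cohort with a `group` factor column
#'   (levels poor / normal / long_term).
#' @export
assign_response_groups <- function(cohort, thresholds = group_thresholds()) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "pfs_months") %in% names(cohort)))
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient identifiers")
  pfs <- cohort$pfs_months
  if (all(is.na(pfs))) stop("PFS is unknown for every patient")
  if (any(pfs <= 0, na.rm = TRUE))
    stop("non-positive PFS for: ",
         paste(cohort$patient_id[which(pfs <= 0)], collapse = ", "))
  long <- if (thresholds$long_min_inclusive) pfs >= thresholds$long_min
          else pfs > thresholds$long_min
  grp <- ifelse(pfs <= thresholds$poor_max, "poor",
                ifelse(long, "long_term", "normal"))
  cohort$group <- factor(grp, levels = response_levels)
  cohort
}

#' Read a cohort table
#'
#' TSV/CSV with columns `patient_id`, `pfs_months`, `progressed` (and
#' optionally `group`); blank, `"NA"` and `"NaN"` cells are missing.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("patient_id", "pfs_months") %in% names(df)))
    stop("cohort table needs patient_id and pfs_months columns: ", path)
  df$patient_id <- as.character(df$patient_id)
  df$pfs_months <- as.numeric(df$pfs_months)
  if ("progressed" %in% names(df)) df$progressed <- as.logical(df$progressed)
  if ("group" %in% names(df)) df$group <- factor(df$group, response_levels)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient identifiers in ", path)
  df
}

#' Write a cohort table
#' @param cohort data.frame.
#' @param path output path; `.csv` selects comma delimiting.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = detect_delim(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
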