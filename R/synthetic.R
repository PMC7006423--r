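#' Specification for a synthetic plasma-proteomics cohort
#'
#' Defines the statistical structure of a simulated targeted-proteomics
#' cohort: three duration-of-response groups, a monitored protein set of
#' which only a subset is reliably detected, a small planted prognostic
#' signal with direction-consistent group mean shifts, block-correlated
#' proteins, completely-at-random missingness, and PFS values drawn within
#' group-consistent ranges. Defaults emulate the motivating cohort: 5 poor /
#' 10 normal / 7 long-term responders, 327 monitored proteins of which 126
#' are detected.
#'
#' @param n_poor,n_normal,n_long group sizes.
#' @param n_proteins_monitored,n_proteins_detected monitored and detected
#'   protein counts; the difference is emitted with >50% missingness so the
#'   default detection filter removes it.
#' @param n_signal number of planted prognostic proteins.
#' @param effect_long_vs_normal,effect_long_vs_poor standardized mean shifts
#'   (within-group SD units) of signal proteins, long-term minus normal and
#'   long-term minus poor; both positive so fold-change signs are concordant.
#' @param block_size,block_rho size and within-block correlation of the
#'   compound-symmetric protein blocks.
#' @param missing_rate MCAR missingness rate on detected proteins; per
#'   protein the missing count is capped so every detected protein passes a
#'   `detect_guarantee` completeness filter by construction.
#' @param missing_mode `"mcar"` or `"censor"` (intensity-dependent: the
#'   lowest values are preferentially missing, a left-censoring stress mode).
#' @param detect_guarantee completeness level detected proteins are
#'   guaranteed to reach (default 0.8, matching [filter_detected()]).
#' @param pfs_poor,pfs_normal,pfs_long `(min, max)` PFS ranges in months.
#' @return A `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(n_poor = 5, n_normal = 10, n_long = 7,
                           n_proteins_monitored = 327,
                           n_proteins_detected = 126,
                           n_signal = 5,
                           effect_long_vs_normal = 1.0,
                           effect_long_vs_poor = 1.5,
                           block_size = 5, block_rho = 0.5,
                           missing_rate = 0.05,
                           missing_mode = c("mcar", "censor"),
                           detect_guarantee = 0.8,
                           pfs_poor = c(0.5, 3), pfs_normal = c(3.5, 23),
                           pfs_long = c(24, 44)) {
  missing_mode <- match.arg(missing_mode)
  spec <- list(n_poor = n_poor, n_normal = n_normal, n_long = n_long,
               n_proteins_monitored = n_proteins_monitored,
               n_proteins_detected = n_proteins_detected,
               n_signal = n_signal,
               effect_long_vs_normal = effect_long_vs_normal,
               effect_long_vs_poor = effect_long_vs_poor,
               block_size = block_size, block_rho = block_rho,
               missing_rate = missing_rate, missing_mode = missing_mode,
               detect_guarantee = detect_guarantee,
               pfs_poor = pfs_poor, pfs_normal = pfs_normal,
               pfs_long = pfs_long)
  thr <- group_thresholds()
  if (n_signal > n_proteins_detected)
    stop("n_signal exceeds the number of detected proteins")
  if (n_proteins_detected > n_proteins_monitored)
    stop("more detected than monitored proteins")
  if (block_size > n_proteins_detected)
    stop("block_size exceeds the number of detected proteins")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0, 1)")
  if (pfs_poor[2] > thr$poor_max || pfs_normal[1] <= thr$poor_max ||
      pfs_normal[2] >= thr$long_min || pfs_long[1] < thr$long_min)
    stop("PFS ranges must respect the default group thresholds")
  structure(spec, class = "synthetic_spec")
}

# Group mean of a signal protein: normal responders at 0, long-term shifted up
# by effect_long_vs_normal, poor shifted so that long-vs-poor equals
# effect_long_vs_poor. Direction-consistent by construction.
signal_group_means <- function(spec) {
  c(poor = spec$effect_long_vs_normal - spec$effect_long_vs_poor,
    normal = 0,
    long_term = spec$effect_long_vs_normal)
}

#' Generate a synthetic cohort with planted prognostic signal
#'
#' Detected proteins are drawn from a block-structured multivariate normal
#' (compound-symmetric blocks, unit marginal variance, generated by a shared
#' block factor); signal proteins are placed in distinct blocks and receive
#' the spec's standardized group mean shifts. Monitored-but-undetected
#' proteins are emitted with >50% missingness so the default detection
#' filter removes them. PFS is uniform within each group's range;
#' progression is observed for poor and normal responders while long-term
#' responders are censored with probability 1/2 (still on treatment at
#' cutoff). Fully reproducible from `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return A list with elements `matrix` ([expression_matrix()]), `cohort`
#'   (data.frame with group assignments) and `truth` (planted signal protein
#'   ids and their true group means).
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(seed, "synthetic"), {
    n <- spec$n_poor + spec$n_normal + spec$n_long
    groups <- factor(rep(response_levels,
                         c(spec$n_poor, spec$n_normal, spec$n_long)),
                     levels = response_levels)
    pd <- spec$n_proteins_detected
    pu <- spec$n_proteins_monitored - pd

    # block factor model: x_ij = sqrt(rho) f_{block(j)} + sqrt(1-rho) e_ij
    n_blocks <- ceiling(pd / spec$block_size)
    block_of <- rep(seq_len(n_blocks), each = spec$block_size)[seq_len(pd)]
    f <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    e <- matrix(stats::rnorm(n * pd), n, pd)
    vals <- sqrt(spec$block_rho) * f[, block_of, drop = FALSE] +
      sqrt(1 - spec$block_rho) * e

    # plant signal proteins, one per block, spread across distinct blocks
    signal_idx <- integer(0)
    if (spec$n_signal > 0) {
      blocks_used <- seq_len(min(spec$n_signal, n_blocks))
      signal_idx <- vapply(blocks_used, function(b) which(block_of == b)[1L],
                           integer(1))
      if (spec$n_signal > n_blocks)
        signal_idx <- c(signal_idx,
                        setdiff(seq_len(pd), signal_idx)[
                          seq_len(spec$n_signal - n_blocks)])
      mu <- signal_group_means(spec)
      shift <- mu[as.character(groups)]
      for (j in signal_idx) vals[, j] <- vals[, j] + shift
    }

    prot_ids <- sprintf("P%03d", seq_len(spec$n_proteins_monitored))
    det_ids <- prot_ids[seq_len(pd)]

    # MCAR missingness on detected proteins, capped per protein so every
    # detected protein is guaranteed to pass the detection filter
    cap <- floor((1 - spec$detect_guarantee) * n)
    for (j in seq_len(pd)) {
      k <- min(stats::rbinom(1L, n, spec$missing_rate), cap)
      if (k > 0) {
        miss <- if (spec$missing_mode == "censor")
          order(vals[, j])[seq_len(k)] else sample.int(n, k)
        vals[miss, j] <- NA_real_
      }
    }

    # monitored-but-undetected proteins: mostly missing noise
    if (pu > 0) {
      und <- matrix(stats::rnorm(n * pu), n, pu)
      for (j in seq_len(pu)) {
        k <- max(stats::rbinom(1L, n, 0.7), floor(n / 2) + 1L)
        und[sample.int(n, min(k, n)), j] <- NA_real_
      }
      vals <- cbind(vals, und)
    }

    sample_ids <- sprintf("PT%02d", seq_len(n))
    mat <- expression_matrix(vals, sample_ids = sample_ids,
                             protein_ids = prot_ids,
                             meta = list(generator = "plasmasig synthetic",
                                         seed = seed))

    draw_pfs <- function(k, range) stats::runif(k, range[1], range[2])
    pfs <- c(draw_pfs(spec$n_poor, spec$pfs_poor),
             draw_pfs(spec$n_normal, spec$pfs_normal),
             draw_pfs(spec$n_long, spec$pfs_long))
    progressed <- c(rep(TRUE, spec$n_poor + spec$n_normal),
                    stats::runif(spec$n_long) < 0.5)
    cohort <- data.frame(patient_id = sample_ids, pfs_months = pfs,
                         progressed = progressed,
                         stringsAsFactors = FALSE)
    cohort <- assign_response_groups(cohort)

    truth <- list(signal_proteins = det_ids[signal_idx],
                  group_means = if (length(signal_idx))
                    signal_group_means(spec) else
                      stats::setNames(numeric(3), response_levels))
    list(matrix = mat, cohort = cohort, truth = truth)
  })
}

#' Generate a null cohort (no planted signal)
#'
#' Identical to [generate_cohort()] with all effects forced to zero and an
#' empty signal set; labels then carry no information about expression.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()]; `truth$signal_proteins` is empty.
#' @export
generate_null_cohort <- function(spec = synthetic_spec(), seed = 1L) {
  spec$n_signal <- 0L
  spec$effect_long_vs_normal <- 0
  spec$effect_long_vs_poor <- 0
  generate_cohort(spec, seed)
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression matrix, cohort table and ground-truth signal list
#' as TSV plus the generating spec (YAML when the yaml package is
#' available, JSON otherwise).
#'
#' @param sim output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param spec the generating [synthetic_spec()], stored for provenance.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(sim, dir, spec = synthetic_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$matrix, file.path(dir, "matrix.tsv"))
  write_cohort(sim$cohort, file.path(dir, "cohort.tsv"))
  utils::write.table(
    data.frame(protein_id = sim$truth$signal_proteins),
    file.path(dir, "truth.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  plain <- unclass(spec)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(plain, file.path(dir, "spec.yaml"))
  } else {
    jsonlite::write_json(plain, file.path(dir, "spec.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
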