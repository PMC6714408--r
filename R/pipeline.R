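#' Assemble and validate a pipeline configuration
#'
#' Inputs may be in-memory data.frames or file paths (calls in PennCNV
#' format via [read_penncnv()]; visits and covariates as TSV via
#' [read_tsv()]). Referenced paths must exist at validation time.
#'
#' @param calls CNV calls data.frame, or path to a PennCNV file.
#' @param visits clinical visits data.frame, or path to a phenotype TSV.
#' @param covariates covariate data.frame, or path to a covariate TSV.
#' @param sample_ids cohort sample ids; defaults to the covariate table's.
#' @param min_snps_per_call minimum probes per retained call.
#' @param max_calls_per_sample per-sample call-count QC threshold.
#' @param min_carrier_freq common-segment carrier-frequency threshold.
#' @param hwe_alpha Hardy-Weinberg exclusion threshold.
#' @param fdr_q false-discovery-rate threshold.
#' @param orientation outcome orientation for the linear CDAI model.
#' @param models association models to run.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, visits, covariates, sample_ids = NULL,
                            min_snps_per_call = 4L,
                            max_calls_per_sample = 100L,
                            min_carrier_freq = 0.05, hwe_alpha = 0.05,
                            fdr_q = 0.05, orientation = "improvement",
                            models = c("logistic_eular", "linear_cdai")) {
  load_input <- function(x, reader, what) {
    if (is.character(x)) {
      if (!file.exists(x)) stop(sprintf("%s file not found: %s", what, x))
      reader(x)
    } else x
  }
  calls <- load_input(calls, read_penncnv, "calls")
  visits <- load_input(visits, read_tsv, "visits")
  covariates <- load_input(covariates, read_tsv, "covariates")
  if (any(is.na(covariates)))
    stop("covariate table contains missing values; complete cases required")
  if (min_carrier_freq < 0 || min_carrier_freq > 1)
    stop("min_carrier_freq must be in [0, 1]")
  if (hwe_alpha < 0 || hwe_alpha > 1) stop("hwe_alpha must be in [0, 1]")
  if (fdr_q <= 0 || fdr_q > 1) stop("fdr_q must be in (0, 1]")
  if (is.null(sample_ids)) sample_ids <- as.character(covariates$sample_id)
  structure(list(calls = calls, visits = visits, covariates = covariates,
                 sample_ids = sample_ids,
                 min_snps_per_call = min_snps_per_call,
                 max_calls_per_sample = max_calls_per_sample,
                 min_carrier_freq = min_carrier_freq,
                 hwe_alpha = hwe_alpha, fdr_q = fdr_q,
                 orientation = orientation, models = models),
            class = "pipeline_config")
}

#' Run the end-to-end CNV/response association pipeline
#'
#' Stages: per-sample call-count QC, multi-sample segmentation,
#' class/frequency/HWE filtering, disease-activity scoring with EULAR
#' labelling, covariate-adjusted association (logistic non-response and
#' linear CDAI-change models), and Benjamini-Hochberg FDR. The returned
#' report counts every stage; by construction the counts satisfy
#' `common segments <= segments` and `significant <= tested`.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `report` (named stage
#'   counts), `qc`, `segments` (full `segment_matrix`), `filtered`
#'   (common segments), `labels`, and `associations`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  calls <- config$calls
  small <- calls$num_snps < config$min_snps_per_call
  calls <- calls[!small, , drop = FALSE]

  qc <- sample_cnv_qc(calls, config$sample_ids, config$max_calls_per_sample)
  labels <- build_response_labels(config$visits)
  keep <- intersect(qc$kept, labels$sample_id)

  calls <- qc$calls[qc$calls$sample_id %in% keep, , drop = FALSE]
  labels <- labels[match(keep, labels$sample_id), ]
  covariates <- config$covariates[
    match(keep, config$covariates$sample_id), , drop = FALSE]
  if (any(is.na(covariates$sample_id)))
    stop("covariate table is missing samples: ",
         paste(utils::head(setdiff(keep, config$covariates$sample_id), 5),
               collapse = ", "))

  sm <- segment_cnvs(calls, keep)
  common <- filter_segments(sm, config$min_carrier_freq, config$hwe_alpha)
  assoc <- if (nrow(common$segments)) {
    assoc_all_segments(common, labels, covariates, config$models,
                       config$fdr_q, config$orientation)
  } else NULL

  n_sig <- if (is.null(assoc)) stats::setNames(
    integer(length(config$models)), config$models)
  else tapply(assoc$fdr_significant, assoc$model, sum)

  report <- list(
    n_samples = length(config$sample_ids),
    n_calls = nrow(calls),
    n_samples_excluded_qc = nrow(qc$excluded),
    n_samples_analyzed = length(keep),
    n_segments = nrow(sm$segments),
    n_common_segments = nrow(common$segments),
    n_significant = n_sig)
  structure(list(report = report, qc = qc, segments = sm,
                 filtered = common, labels = labels,
                 associations = assoc),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("CNV / drug-response pipeline\n")
  cat(sprintf("  samples: %d (%d excluded by call-count QC, %d analyzed)\n",
              r$n_samples, r$n_samples_excluded_qc, r$n_samples_analyzed))
  cat(sprintf("  calls: %d -> segments: %d -> common segments: %d\n",
              r$n_calls, r$n_segments, r$n_common_segments))
  for (m in names(r$n_significant))
    cat(sprintf("  FDR-significant (%s): %d\n", m, r$n_significant[[m]]))
  invisible(x)
}

#' Simulate a synthetic cohort and run the full pipeline on it
#'
#' Convenience wrapper: [simulate_cohort()] + [simulate_cnv_calls()] +
#' [run_pipeline()].
#'
#' @param config a [sim_config()].
#' @param ... passed to [pipeline_config()].
#' @return a `pipeline_result`, with the simulation attached as
#'   `$simulation`.
#' @export
run_synthetic_pipeline <- function(config = sim_config(), ...) {
  sim <- simulate_cohort(config)
  calls <- simulate_cnv_calls(sim$genotypes, config)
  pc <- pipeline_config(calls = calls, visits = sim$visits,
                        covariates = sim$covariates,
                        sample_ids = sim$covariates$sample_id, ...)
  out <- run_pipeline(pc)
  out$simulation <- sim
  out
}
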