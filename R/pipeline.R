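## End-to-end pipeline: configuration, stage composition, run manifest.
## A config drives either a synthetic cohort (a SimParams block) or real
## inputs (cohort TSV, optional summary statistics); exactly one of the two.

.configError <- function(...) stop(..., call. = FALSE)

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a path to a JSON file) with exactly
#' one of \code{simulate} (a list of \code{\link{simParams}} arguments) or
#' \code{inputs} (paths: \code{cohort}, optionally \code{sumstats}), a
#' mandatory integer \code{seed}, and optional blocks \code{thresholds}
#' (\code{p_thresh}, \code{r2_thresh}, \code{window_kb}, \code{alpha}),
#' \code{covariates} (adjustment columns for the MR stage) and
#' \code{powersim} (\code{effect_grid}, \code{n_replicates}, \code{alpha}).
#'
#' @param config named list or path to a JSON config file.
#' @return the validated config list (with defaults filled in).
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .configError("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) .configError("config must be a list or a JSON path")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    .configError("config must contain exactly one of 'simulate' or 'inputs'")
  if (is.null(config$seed)) .configError("config must contain a 'seed'")
  config$seed <- as.integer(config$seed)
  thr <- config$thresholds
  config$thresholds <- list(
    p_thresh = thr$p_thresh %||% 5e-8,
    r2_thresh = thr$r2_thresh %||% 0.001,
    window_kb = thr$window_kb %||% 1000,
    alpha = thr$alpha %||% 0.05)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input), the
#' observational stage (univariable scan + multivariable fit + pairwise
#' association matrix), the PRS stage (clumping, harmonization, scoring --
#' from supplied summary statistics, or statistics synthesized from the
#' generative weights in simulation mode), the proxy GxE MR stage
#' (single-SNP and PRS instruments, control checks), and optionally a power
#' simulation. All result tables are written as TSV under \code{out_dir}
#' together with a JSON run manifest (seed, package version, config echo,
#' row counts at each filter step). Runs are deterministic: the same config
#' yields byte-identical outputs.
#'
#' @param config named list or JSON path; see
#'   \code{\link{readPipelineConfig}}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config, out_dir) {
  config <- readPipelineConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package = "proxyGxEMR",
                   version = as.character(packageVersion("proxyGxEMR")),
                   config = config, counts = list())
  count <- function(name, value) manifest$counts[[name]] <<- value

  ## --- cohort -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    params <- do.call(simParams,
                      c(config$simulate, list(seed = config$seed)))
    cohort <- generateCohort(params)
    writeCohort(cohort, file.path(out_dir, "cohort.tsv"))
  } else {
    cohort <- readCohort(config$inputs$cohort)
  }
  count("cohort_rows", ncol(cohort))
  ph <- phenotypes(cohort)

  ## --- observational ------------------------------------------------------
  specs <- defaultPredictorSpecs()
  specs <- specs[specs$name %in% colnames(ph), , drop = FALSE]
  uni <- univariableScan(ph, specs)
  uni$model_type <- "univariable"
  multi <- multivariableFit(ph, specs)
  mres <- multi$results
  mres$model_id <- "multivariable"
  mres$model_type <- "multivariable"
  obs <- rbind(uni, mres)
  writeResultTSV(obs, file.path(out_dir, "observational.tsv"))
  writeResultTSV(associationMatrix(ph, specs$name),
                 file.path(out_dir, "association_matrix.tsv"))
  count("multivariable_complete_cases", multi$n_used)

  ## --- prs ----------------------------------------------------------------
  panel <- t(offspringDosage(cohort))
  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  if (!is.null(config$inputs$sumstats)) {
    ss <- readSumstats(config$inputs$sumstats)
    stats <- ss$records
    count("sumstats_records", nrow(stats))
    count("sumstats_rejects", nrow(ss$rejects))
  } else {
    # synthesize summary statistics from the generative model
    stats <- data.frame(snp_id = rd$snp_id, chrom = rd$chrom, pos = rd$pos,
                        effect_allele = rd$effect_allele,
                        other_allele = rd$other_allele,
                        beta = rd$weight, se = 0.01, p = 1e-10,
                        stringsAsFactors = FALSE)
  }
  thr <- config$thresholds
  clump <- clumpVariants(stats, panel, p_thresh = thr$p_thresh,
                         r2_thresh = thr$r2_thresh,
                         window_kb = thr$window_kb)
  count("clump_index_snps", length(clump@index_snps))
  harm <- harmonizeAlleles(
    stats[stats$snp_id %in% clump@index_snps, , drop = FALSE],
    setNames(rd$effect_allele %||% rep("A", nrow(rd)), rd$snp_id))
  count("harmonize_dropped", nrow(harm$dropped))
  prs <- computePRS(panel, harm$weights)
  writeResultTSV(data.frame(IID = colnames(cohort), PRS = prs),
                 file.path(out_dir, "prs.tsv"))
  writeResultTSV(clumpReport(clump, stats),
                 file.path(out_dir, "clump_report.tsv"))

  ## --- proxy MR -----------------------------------------------------------
  covs <- unlist(config$covariates) %||% NULL
  snp1 <- rd$snp_id[1]
  fits <- list(
    snp = proxyMR(cohort, snp1, covariates = covs),
    prs = proxyMR(cohort, prs, covariates = covs, instrument_label = "PRS"))
  assoc <- do.call(rbind, lapply(fits, function(f)
    do.call(rbind, lapply(f$associations, as.data.frame))))
  wald <- do.call(rbind, lapply(fits, function(f)
    do.call(rbind, lapply(f$wald, as.data.frame))))
  corr <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(f$corrected)))
  writeResultTSV(assoc, file.path(out_dir, "stratum_associations.tsv"))
  writeResultTSV(wald, file.path(out_dir, "wald_estimates.tsv"))
  writeResultTSV(corr, file.path(out_dir, "corrected_estimates.tsv"))
  ctl <- controlChecks(cohort, snp1, covariates = covs)
  writeResultTSV(ctl, file.path(out_dir, "control_checks.tsv"))
  sm <- ph$maternal_smoked
  count("stratum_exposed", sum(sm == 1, na.rm = TRUE))
  count("stratum_unexposed", sum(sm == 0, na.rm = TRUE))
  count("stratum_dropped", sum(is.na(sm)))

  ## --- power simulation (optional) ---------------------------------------
  power <- NULL
  if (!is.null(config$powersim)) {
    ps <- config$powersim
    base <- if (!is.null(config$simulate))
      do.call(simParams, c(config$simulate, list(seed = config$seed)))
    else simParams(seed = config$seed)
    scen <- powerScenario(
      sim = base,
      effect_grid = unlist(ps$effect_grid) %||% c(1, 1.2, 1.44),
      n_replicates = ps$n_replicates %||% 200,
      alpha = ps$alpha %||% thr$alpha,
      estimator = ps$estimator %||% "corrected")
    power <- runPowerScenario(scen, master_seed = config$seed)
    writeResultTSV(power, file.path(out_dir, "power.tsv"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, observational = obs, clump = clump,
                 prs = prs, mr = fits, controls = ctl, power = power,
                 manifest = manifest))
}
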