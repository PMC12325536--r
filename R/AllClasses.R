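#' @import methods
#' @importFrom stats as.formula binomial chisq.test coef complete.cases cor
#'   glm lm logLik pchisq plogis pnorm qlogis qnorm rbinom rnorm runif sd var
#'   vcov setNames
#' @importFrom utils read.table write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom jsonlite read_json write_json
NULL

Z975 <- stats::qnorm(0.975)

#' Simulation parameters for a synthetic mother--offspring cohort
#'
#' \code{SimParams} bundles every knob of the generative model behind
#' \code{\link{generateCohort}}: allele frequencies and per-allele effects on a
#' maternal quantitative exposure (cigarettes smoked per day in pregnancy),
#' the smoking-initiation model (including the genotype-to-initiation path
#' that creates collider bias when stratifying on smoking status), a latent
#' standard-normal confounder U with configurable path coefficients, the
#' binary outcome model (left-handedness) with separate causal and
#' pleiotropic effects, and a continuous negative-control outcome
#' (birthweight).
#'
#' Defaults describe a UK-Biobank-like world: one biallelic SNP with
#' effect-allele frequency 0.33, a per-allele effect of 0.86 cigarettes/day
#' (about 0.4\% of exposure variance among smokers), 30.6\% of mothers
#' smoking in pregnancy, a 9.8\% left-handedness base rate, and a mean
#' birthweight of 3.33 kg. All causal, pleiotropic, collider and confounder
#' paths default to zero (the full null).
#'
#' @slot n_pairs number of mother--offspring pairs (>= 0).
#' @slot allele_freqs per-SNP effect-allele frequency, strictly in (0,1).
#' @slot snp_weights per-SNP effect on cigarettes/day per effect allele.
#' @slot exposure_mean baseline cigarettes/day among smoking mothers.
#' @slot exposure_sd residual SD of cigarettes/day among smokers (>= 0).
#' @slot init_base baseline probability that the mother smokes in pregnancy.
#' @slot init_per_allele log-odds change in smoking initiation per maternal
#'   effect allele (0 disables the collider pathway).
#' @slot confounder_sd SD of the latent confounder U.
#' @slot conf_on_init,conf_on_outcome,conf_on_birthweight path coefficients
#'   of U on initiation (log-odds), handedness (log-odds) and birthweight (kg).
#' @slot outcome_base_logit baseline log-odds of left-handedness.
#' @slot causal_beta log-odds of left-handedness per cigarette/day; acts only
#'   when the mother smoked.
#' @slot pleiotropy_beta direct log-odds of left-handedness per offspring
#'   effect allele, bypassing maternal smoking.
#' @slot bw_base,bw_theta,bw_sd birthweight intercept (kg), change per
#'   cigarette/day, and residual SD.
#' @slot spousal_cor maternal--paternal dosage correlation (0 = random mating).
#' @slot seed integer RNG seed; identical params + seed give a bit-identical
#'   cohort.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{simParams}}
#' @export
setClass("SimParams", representation(
  n_pairs = "numeric",
  allele_freqs = "numeric",
  snp_weights = "numeric",
  exposure_mean = "numeric",
  exposure_sd = "numeric",
  init_base = "numeric",
  init_per_allele = "numeric",
  confounder_sd = "numeric",
  conf_on_init = "numeric",
  conf_on_outcome = "numeric",
  conf_on_birthweight = "numeric",
  outcome_base_logit = "numeric",
  causal_beta = "numeric",
  pleiotropy_beta = "numeric",
  bw_base = "numeric",
  bw_theta = "numeric",
  bw_sd = "numeric",
  spousal_cor = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@n_pairs) != 1L || is.na(object@n_pairs) ||
      object@n_pairs < 0 || object@n_pairs != floor(object@n_pairs))
    msg <- c(msg, "'n_pairs' must be a single non-negative integer")
  if (length(object@allele_freqs) < 1L ||
      any(!is.finite(object@allele_freqs)) ||
      any(object@allele_freqs <= 0 | object@allele_freqs >= 1))
    msg <- c(msg, "'allele_freqs' must lie strictly inside (0, 1)")
  if (length(object@snp_weights) != length(object@allele_freqs))
    msg <- c(msg, "'snp_weights' must match 'allele_freqs' in length")
  if (object@exposure_sd < 0) msg <- c(msg, "'exposure_sd' must be >= 0")
  if (object@bw_sd < 0) msg <- c(msg, "'bw_sd' must be >= 0")
  if (object@confounder_sd < 0) msg <- c(msg, "'confounder_sd' must be >= 0")
  if (object@init_base <= 0 || object@init_base >= 1)
    msg <- c(msg, "'init_base' must lie strictly inside (0, 1)")
  if (object@spousal_cor < 0 || object@spousal_cor >= 1)
    msg <- c(msg, "'spousal_cor' must lie in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' User-facing constructor for \code{\linkS4class{SimParams}}; any slot can be
#' overridden by name, everything else keeps its UK-Biobank-like default.
#'
#' @param n_pairs number of mother--offspring pairs.
#' @param allele_freqs per-SNP effect-allele frequencies in (0,1).
#' @param snp_weights per-SNP cigarettes/day per effect allele.
#' @param exposure_mean,exposure_sd mean and residual SD of cigarettes/day
#'   among smoking mothers.
#' @param init_base baseline probability the mother smoked in pregnancy.
#' @param init_per_allele log-odds of smoking initiation per effect allele.
#' @param confounder_sd SD of the latent confounder U.
#' @param conf_on_init,conf_on_outcome,conf_on_birthweight path coefficients
#'   of U.
#' @param outcome_base_logit baseline log-odds of left-handedness.
#' @param causal_beta causal log-odds of left-handedness per cigarette/day.
#' @param pleiotropy_beta direct log-odds per offspring effect allele.
#' @param bw_base,bw_theta,bw_sd birthweight model: intercept (kg), change per
#'   cigarette/day, residual SD.
#' @param spousal_cor maternal--paternal dosage correlation.
#' @param seed integer RNG seed.
#' @return a validated \code{SimParams} object.
#' @examples
#' p <- simParams(n_pairs = 1000, seed = 7)
#' coh <- generateCohort(p)
#' @export
simParams <- function(n_pairs = 10000,
                      allele_freqs = 0.33,
                      snp_weights = 0.86,
                      exposure_mean = 13.7,
                      exposure_sd = 9,
                      init_base = 0.306,
                      init_per_allele = 0,
                      confounder_sd = 1,
                      conf_on_init = 0,
                      conf_on_outcome = 0,
                      conf_on_birthweight = 0,
                      outcome_base_logit = qlogis(0.0982),
                      causal_beta = 0,
                      pleiotropy_beta = 0,
                      bw_base = 3.33,
                      bw_theta = -0.015,
                      bw_sd = 0.5,
                      spousal_cor = 0,
                      seed = 1L) {
  new("SimParams",
      n_pairs = as.numeric(n_pairs), allele_freqs = as.numeric(allele_freqs),
      snp_weights = as.numeric(snp_weights),
      exposure_mean = exposure_mean, exposure_sd = exposure_sd,
      init_base = init_base, init_per_allele = init_per_allele,
      confounder_sd = confounder_sd, conf_on_init = conf_on_init,
      conf_on_outcome = conf_on_outcome,
      conf_on_birthweight = conf_on_birthweight,
      outcome_base_logit = outcome_base_logit, causal_beta = causal_beta,
      pleiotropy_beta = pleiotropy_beta, bw_base = bw_base,
      bw_theta = bw_theta, bw_sd = bw_sd, spousal_cor = spousal_cor,
      seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@n_pairs, "mother-offspring pairs,",
      length(object@allele_freqs), "SNP(s), seed", object@seed, "\n")
  cat("  exposure: mean", object@exposure_mean, "sd", object@exposure_sd,
      "cigs/day; P(smoked) base", object@init_base, "\n")
  cat("  paths: causal", object@causal_beta,
      "| pleiotropy", object@pleiotropy_beta,
      "| init/allele", object@init_per_allele,
      "| U -> (init, outcome, bw) =",
      paste(c(object@conf_on_init, object@conf_on_outcome,
              object@conf_on_birthweight), collapse = ", "), "\n")
})

#' Mother--offspring cohort container
#'
#' \code{MRCohort} extends \code{SummarizedExperiment}: rows are SNPs
#' (with effect allele, frequency and genomic coordinates in \code{rowData}),
#' columns are offspring, and the assays hold additive dosages (0/1/2 counts
#' of the effect allele) for the offspring and -- when generated
#' synthetically -- the latent maternal and paternal dosages retained for
#' oracle checks. Phenotypes and early-life covariates (maternal smoking in
#' pregnancy, cigarettes/day, handedness, birthweight, sex, birth
#' year/month, breastfeeding, multiple birth, country, Townsend score, and
#' the latent confounder) live in \code{colData}.
#'
#' The class invariant ties exposure fields together: \code{cigs_per_day} is
#' missing exactly for mothers who did not smoke in pregnancy.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{offspringDosage}},
#'   \code{\link{stratifyCohort}}
#' @export
setClass("MRCohort", contains = "SummarizedExperiment")

setValidity("MRCohort", function(object) {
  msg <- character()
  for (a in intersect(c("offspringDosage", "maternalDosage",
                        "paternalDosage"),
                      SummarizedExperiment::assayNames(object))) {
    d <- SummarizedExperiment::assay(object, a)
    if (any(!is.na(d) & !(d %in% 0:2)))
      msg <- c(msg, sprintf("assay '%s' must contain dosages in {0,1,2}", a))
  }
  cd <- SummarizedExperiment::colData(object)
  if (all(c("maternal_smoked", "cigs_per_day") %in% colnames(cd))) {
    sm <- cd$maternal_smoked
    ok <- is.na(sm) | (is.na(cd$cigs_per_day) == (sm == 0))
    if (!all(ok))
      msg <- c(msg,
               "'cigs_per_day' must be missing exactly when maternal_smoked = 0")
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for MRCohort dosage assays and phenotypes
#'
#' \code{offspringDosage}, \code{maternalDosage} and \code{paternalDosage}
#' return the SNP-by-sample dosage matrices; \code{phenotypes} returns
#' \code{colData} as a plain \code{data.frame}; \code{simParams} returns the
#' \code{\linkS4class{SimParams}} a synthetic cohort was generated from (or
#' \code{NULL}).
#'
#' @param x an \code{\linkS4class{MRCohort}}.
#' @return a matrix, \code{data.frame}, or \code{SimParams}.
#' @aliases maternalDosage paternalDosage phenotypes
#' @export
setGeneric("offspringDosage", function(x) standardGeneric("offspringDosage"))
#' @rdname offspringDosage
#' @export
setGeneric("maternalDosage", function(x) standardGeneric("maternalDosage"))
#' @rdname offspringDosage
#' @export
setGeneric("paternalDosage", function(x) standardGeneric("paternalDosage"))
#' @rdname offspringDosage
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

.getAssay <- function(x, name) {
  if (!name %in% SummarizedExperiment::assayNames(x))
    stop("cohort has no '", name, "' assay", call. = FALSE)
  SummarizedExperiment::assay(x, name)
}

#' @rdname offspringDosage
setMethod("offspringDosage", "MRCohort",
          function(x) .getAssay(x, "offspringDosage"))
#' @rdname offspringDosage
setMethod("maternalDosage", "MRCohort",
          function(x) .getAssay(x, "maternalDosage"))
#' @rdname offspringDosage
setMethod("paternalDosage", "MRCohort",
          function(x) .getAssay(x, "paternalDosage"))
#' @rdname offspringDosage
setMethod("phenotypes", "MRCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname offspringDosage
#' @export
cohortSimParams <- function(x) S4Vectors::metadata(x)$params

setMethod("show", "MRCohort", function(object) {
  cat("MRCohort:", ncol(object), "offspring x", nrow(object), "SNP(s)\n")
  cd <- SummarizedExperiment::colData(object)
  if ("maternal_smoked" %in% colnames(cd) && ncol(object) > 0) {
    sm <- cd$maternal_smoked
    cat(sprintf("  maternal smoking in pregnancy: %.1f%% (%d missing)\n",
                100 * mean(sm == 1, na.rm = TRUE), sum(is.na(sm))))
  }
  if ("left_handed" %in% colnames(cd) && ncol(object) > 0)
    cat(sprintf("  left-handed: %.2f%%\n",
                100 * mean(cd$left_handed == 1, na.rm = TRUE)))
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

#' Stratum-specific genetic association
#'
#' One regression coefficient of an instrument (single SNP dosage or PRS) on
#' an outcome or exposure, estimated within a maternal-smoking stratum. The
#' coefficient is a log-odds ratio for binary outcomes and a raw slope for
#' continuous ones.
#'
#' @slot stratum "exposed", "unexposed" or another stratum label.
#' @slot instrument instrument label (e.g. SNP id or "PRS").
#' @slot beta,se,p coefficient, standard error, two-sided Wald p.
#' @slot n complete-case sample size.
#' @slot covariate_set "unadjusted" or "adjusted".
#' @slot family "logistic" or "linear".
#' @export
setClass("StratumAssociation", representation(
  stratum = "character", instrument = "character",
  beta = "numeric", se = "numeric", p = "numeric", n = "numeric",
  covariate_set = "character", family = "character"))

setValidity("StratumAssociation", function(object) {
  msg <- character()
  if (object@n <= 0) msg <- c(msg, "'n' must be positive")
  if (!is.na(object@se) && object@se <= 0)
    msg <- c(msg, "'se' must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StratumAssociation", function(object) {
  cat(sprintf(
    "StratumAssociation [%s, %s, %s]: beta = %.4g (se %.4g, p = %.3g, n = %d)\n",
    object@instrument, object@stratum, object@covariate_set,
    object@beta, object@se, object@p, as.integer(object@n)))
})

#' Wald-ratio instrumental-variable estimate
#'
#' The causal log-odds of the outcome per unit of exposure (here,
#' left-handedness per cigarette/day), formed as the ratio of the
#' instrument--outcome to the instrument--exposure association, with a
#' first-order delta-method standard error and 95\% normal CI.
#'
#' @slot beta_iv,se_iv estimate and delta-method SE.
#' @slot ci_low,ci_high 95\% normal confidence limits.
#' @slot stratum stratum the numerator was estimated in.
#' @slot instrument instrument label.
#' @seealso \code{\link{waldRatio}}
#' @export
setClass("WaldEstimate", representation(
  beta_iv = "numeric", se_iv = "numeric",
  ci_low = "numeric", ci_high = "numeric",
  stratum = "character", instrument = "character"))

setValidity("WaldEstimate", function(object) {
  if (object@ci_low > object@beta_iv || object@beta_iv > object@ci_high)
    "confidence interval must bracket beta_iv" else TRUE
})

setMethod("show", "WaldEstimate", function(object) {
  cat(sprintf("WaldEstimate [%s, %s]: beta_IV = %.4f (95%% CI %.4f, %.4f)\n",
              object@instrument, object@stratum, object@beta_iv,
              object@ci_low, object@ci_high))
})

#' Pleiotropy-corrected causal estimate
#'
#' The exposed-stratum Wald estimate minus the unexposed-stratum ("no
#' relevance" group) Wald estimate. Under the design's assumptions the
#' unexposed-stratum estimate is pure pleiotropic bias, so the difference is
#' the causal effect corrected for pleiotropy; its SE treats the two strata
#' as independent (disjoint individuals).
#'
#' @slot beta_corrected,se difference and its SE.
#' @slot ci_low,ci_high 95\% normal confidence limits.
#' @slot instrument instrument label.
#' @seealso \code{\link{pleiotropyCorrect}}
#' @export
setClass("CorrectedEstimate", representation(
  beta_corrected = "numeric", se = "numeric",
  ci_low = "numeric", ci_high = "numeric", instrument = "character"))

setMethod("show", "CorrectedEstimate", function(object) {
  cat(sprintf(
    "CorrectedEstimate [%s]: beta = %.4f (95%% CI %.4f, %.4f)\n",
    object@instrument, object@beta_corrected, object@ci_low, object@ci_high))
})

#' Greedy LD-clumping result
#'
#' Index SNPs retained by p-value-ordered greedy clumping, with a map from
#' each absorbed SNP to the index that absorbed it and any SNPs skipped for
#' zero dosage variance.
#'
#' @slot index_snps retained index SNP ids, in selection order.
#' @slot removed named character vector: absorbed SNP -> absorbing index SNP.
#' @slot skipped SNP ids skipped (zero-variance dosage).
#' @slot params list of thresholds used (p_thresh, r2_thresh, window_kb).
#' @seealso \code{\link{clumpVariants}}
#' @export
setClass("ClumpResult", representation(
  index_snps = "character", removed = "character",
  skipped = "character", params = "list"))

setMethod("show", "ClumpResult", function(object) {
  cat(sprintf(
    "ClumpResult: %d index SNP(s), %d absorbed, %d skipped (r2 <= %g, %g kb, p <= %g)\n",
    length(object@index_snps), length(object@removed),
    length(object@skipped), object@params$r2_thresh,
    object@params$window_kb, object@params$p_thresh))
  if (length(object@index_snps))
    cat("  index:", paste(object@index_snps, collapse = ", "), "\n")
})

#' Coerce association and estimate objects to data frames
#'
#' Tidy one-row \code{data.frame} representations, used when writing the
#' stratified-association and causal-estimate tables.
#'
#' @param x a \code{StratumAssociation}, \code{WaldEstimate} or
#'   \code{CorrectedEstimate}.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return a one-row \code{data.frame}.
#' @name as.data.frame-estimates
NULL

#' @rdname as.data.frame-estimates
#' @export
as.data.frame.StratumAssociation <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(instrument = x@instrument, stratum = x@stratum,
             covariate_set = x@covariate_set, family = x@family,
             beta = x@beta, se = x@se,
             ci_low = x@beta - Z975 * x@se, ci_high = x@beta + Z975 * x@se,
             p = x@p, n = x@n, stringsAsFactors = FALSE)
}

#' @rdname as.data.frame-estimates
#' @export
as.data.frame.WaldEstimate <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(instrument = x@instrument, stratum = x@stratum,
             beta_iv = x@beta_iv, se_iv = x@se_iv,
             ci_low = x@ci_low, ci_high = x@ci_high,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame-estimates
#' @export
as.data.frame.CorrectedEstimate <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(instrument = x@instrument, beta_corrected = x@beta_corrected,
             se = x@se, ci_low = x@ci_low, ci_high = x@ci_high,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "StratumAssociation",
          function(x, ...) as.data.frame.StratumAssociation(x, ...))
setMethod("as.data.frame", "WaldEstimate",
          function(x, ...) as.data.frame.WaldEstimate(x, ...))
setMethod("as.data.frame", "CorrectedEstimate",
          function(x, ...) as.data.frame.CorrectedEstimate(x, ...))
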