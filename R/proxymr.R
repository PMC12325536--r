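## Proxy GxE MR causal engine: stratified genetic associations, Wald-ratio
## estimation with delta-method uncertainty, pleiotropy correction by
## between-stratum subtraction, and positive/negative control checks.

#' Stratify a cohort on maternal smoking in pregnancy
#'
#' Splits an \code{\linkS4class{MRCohort}} into the exposed (mother smoked)
#' and unexposed strata. Offspring with missing maternal smoking status are
#' dropped and counted; the two strata plus the dropped rows partition the
#' input.
#'
#' @param cohort an \code{\linkS4class{MRCohort}} with a
#'   \code{maternal_smoked} column.
#' @return list with \code{exposed}, \code{unexposed} (both
#'   \code{MRCohort}) and \code{n_dropped}.
#' @export
stratifyCohort <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  if (!"maternal_smoked" %in% colnames(cd))
    stop("cohort has no 'maternal_smoked' column", call. = FALSE)
  sm <- cd$maternal_smoked
  list(exposed = cohort[, !is.na(sm) & sm == 1],
       unexposed = cohort[, !is.na(sm) & sm == 0],
       n_dropped = sum(is.na(sm)))
}

.resolveInstrument <- function(cohort, instrument) {
  if (is.numeric(instrument)) {
    if (length(instrument) != ncol(cohort))
      stop("numeric instrument must have one value per offspring",
           call. = FALSE)
    return(list(values = instrument, label = "custom"))
  }
  dos <- offspringDosage(cohort)
  if (!instrument %in% rownames(dos))
    stop("instrument SNP '", instrument, "' not found in the cohort",
         call. = FALSE)
  list(values = as.numeric(dos[instrument, ]), label = instrument)
}

#' Association between an instrument and an outcome within a stratum
#'
#' Per-unit-instrument regression coefficient with Wald SE and two-sided p,
#' logistic for binary outcomes and ordinary least squares for continuous
#' ones, on complete cases, optionally adjusting for covariates (e.g. year
#' of birth, sex and genetic principal components).
#'
#' @param cohort an \code{\linkS4class{MRCohort}} (typically one stratum).
#' @param instrument a SNP id present in the cohort, or a numeric vector
#'   (e.g. a PRS) with one value per offspring.
#' @param outcome name of the outcome column in \code{colData}.
#' @param covariates character vector of adjustment column names (encoded
#'   as-is; \code{sex} and other character columns become factors).
#' @param family "logistic" or "linear".
#' @param stratum,instrument_label optional labels stored in the result.
#' @return a \code{\linkS4class{StratumAssociation}}.
#' @export
geneticAssociation <- function(cohort, instrument, outcome = "left_handed",
                               covariates = NULL,
                               family = c("logistic", "linear"),
                               stratum = "all", instrument_label = NULL) {
  family <- match.arg(family)
  inst <- .resolveInstrument(cohort, instrument)
  if (is.null(instrument_label)) instrument_label <- inst$label
  ph <- phenotypes(cohort)
  if (!outcome %in% colnames(ph))
    stop("outcome '", outcome, "' not found", call. = FALSE)
  df <- data.frame(.inst = inst$values, .y = ph[[outcome]])
  for (cv in covariates) {
    if (!cv %in% colnames(ph))
      stop("covariate '", cv, "' not found", call. = FALSE)
    v <- ph[[cv]]
    df[[cv]] <- if (is.character(v)) as.factor(v) else v
  }
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < 2) stop("not enough complete cases", call. = FALSE)
  if (family == "logistic") {
    if (is.character(df$.y) || is.factor(df$.y))
      df$.y <- as.integer(as.factor(df$.y)) - 1L
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  } else {
    fit <- lm(.y ~ ., data = df)
  }
  sm <- summary(fit)$coefficients
  new("StratumAssociation",
      stratum = stratum, instrument = instrument_label,
      beta = sm[".inst", 1], se = sm[".inst", 2], p = sm[".inst", 4],
      n = nrow(df),
      covariate_set = if (length(covariates)) "adjusted" else "unadjusted",
      family = family)
}

#' Wald-ratio instrumental-variable estimate
#'
#' \code{beta_iv = beta_gy / beta_gx} with first-order delta-method SE
#' \code{sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)} and a
#' 95\% normal CI. The numerator is the instrument--outcome association in a
#' stratum; the denominator the instrument--exposure association (here,
#' cigarettes/day among smokers). A weak instrument
#' (\code{|beta_gx| / se_gx} below \code{weak_z}, default 3.16, i.e. F < 10)
#' triggers a warning; \code{beta_gx = 0} is an error.
#'
#' @param beta_gy,se_gy instrument--outcome association and SE (log-odds
#'   scale for binary outcomes).
#' @param beta_gx,se_gx instrument--exposure association and SE.
#' @param stratum,instrument labels carried into the result.
#' @param weak_z weak-instrument z threshold.
#' @return a \code{\linkS4class{WaldEstimate}}.
#' @examples
#' waldRatio(0.02, 0.01, 0.4, 0.05)
#' @export
waldRatio <- function(beta_gy, se_gy, beta_gx, se_gx,
                      stratum = "all", instrument = "instrument",
                      weak_z = sqrt(10)) {
  if (beta_gx == 0)
    stop("instrument-exposure association is zero; Wald ratio undefined",
         call. = FALSE)
  if (abs(beta_gx) / se_gx < weak_z)
    warning(sprintf(
      "weak instrument: |beta_gx|/se_gx = %.2f < %.2f (F < %.0f equivalent)",
      abs(beta_gx) / se_gx, weak_z, weak_z^2), call. = FALSE)
  beta_iv <- beta_gy / beta_gx
  se_iv <- sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  new("WaldEstimate", beta_iv = beta_iv, se_iv = se_iv,
      ci_low = beta_iv - Z975 * se_iv, ci_high = beta_iv + Z975 * se_iv,
      stratum = stratum, instrument = instrument)
}

#' @rdname waldRatio
#' @param gy,gx \code{\linkS4class{StratumAssociation}} objects for the
#'   numerator and denominator (convenience wrapper).
#' @export
waldRatioFromAssociations <- function(gy, gx, weak_z = sqrt(10)) {
  if (gy@instrument != gx@instrument)
    stop("numerator and denominator use different instruments: '",
         gy@instrument, "' vs '", gx@instrument, "'", call. = FALSE)
  waldRatio(gy@beta, gy@se, gx@beta, gx@se,
            stratum = gy@stratum, instrument = gy@instrument,
            weak_z = weak_z)
}

#' Pleiotropy correction by between-stratum subtraction
#'
#' Subtracts the unexposed-stratum ("no relevance" group) Wald estimate
#' from the exposed-stratum estimate. Since the instrument cannot act
#' through maternal smoking in the unexposed stratum, that stratum's
#' estimate measures pleiotropic bias, and the difference estimates the
#' causal effect net of (stratum-constant) pleiotropy. Strata are disjoint
#' individuals, so \code{se = sqrt(se_exposed^2 + se_unexposed^2)}; a 95\%
#' normal CI is attached.
#'
#' @param exposed,unexposed \code{\linkS4class{WaldEstimate}} objects on the
#'   same instrument and scale.
#' @return a \code{\linkS4class{CorrectedEstimate}}.
#' @export
pleiotropyCorrect <- function(exposed, unexposed) {
  if (exposed@instrument != unexposed@instrument)
    stop("strata estimated with different instruments: '",
         exposed@instrument, "' vs '", unexposed@instrument, "'",
         call. = FALSE)
  beta <- exposed@beta_iv - unexposed@beta_iv
  se <- sqrt(exposed@se_iv^2 + unexposed@se_iv^2)
  new("CorrectedEstimate", beta_corrected = beta, se = se,
      ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
      instrument = exposed@instrument)
}

#' Run the full proxy GxE MR analysis on a cohort
#'
#' Stratifies on maternal smoking, estimates the instrument--outcome
#' association in each stratum and the instrument--exposure association
#' (cigarettes/day) among smoking mothers in the whole sample (one shared
#' denominator feeds both strata's Wald ratios), then forms the two Wald
#' estimates and the pleiotropy-corrected difference.
#'
#' @param cohort an \code{\linkS4class{MRCohort}}.
#' @param instrument SNP id or numeric per-offspring instrument (e.g. PRS).
#' @param covariates optional adjustment column names applied to both
#'   numerator and denominator regressions.
#' @param outcome,exposure outcome and exposure column names.
#' @param instrument_label label used in the results.
#' @return list with \code{associations} (per-stratum
#'   \code{StratumAssociation}s plus the denominator), \code{wald}
#'   (exposed/unexposed \code{WaldEstimate}s), and \code{corrected}
#'   (\code{CorrectedEstimate}).
#' @examples
#' coh <- generateCohort(simParams(n_pairs = 4000, seed = 3))
#' fit <- proxyMR(coh, "snp1")
#' fit$corrected
#' @export
proxyMR <- function(cohort, instrument, covariates = NULL,
                    outcome = "left_handed", exposure = "cigs_per_day",
                    instrument_label = NULL) {
  inst <- .resolveInstrument(cohort, instrument)
  if (is.null(instrument_label)) instrument_label <- inst$label
  strata <- stratifyCohort(cohort)
  sm <- phenotypes(cohort)$maternal_smoked
  keep_exp <- !is.na(sm) & sm == 1
  keep_une <- !is.na(sm) & sm == 0
  gy_exp <- geneticAssociation(strata$exposed, inst$values[keep_exp],
                               outcome = outcome, covariates = covariates,
                               family = "logistic", stratum = "exposed",
                               instrument_label = instrument_label)
  gy_une <- geneticAssociation(strata$unexposed, inst$values[keep_une],
                               outcome = outcome, covariates = covariates,
                               family = "logistic", stratum = "unexposed",
                               instrument_label = instrument_label)
  # shared denominator: instrument -> cigarettes/day among smoking mothers
  gx <- geneticAssociation(strata$exposed, inst$values[keep_exp],
                           outcome = exposure, covariates = covariates,
                           family = "linear", stratum = "smokers",
                           instrument_label = instrument_label)
  w_exp <- waldRatioFromAssociations(gy_exp, gx)
  w_une <- waldRatioFromAssociations(gy_une, gx)
  list(associations = list(exposed = gy_exp, unexposed = gy_une,
                           denominator = gx),
       wald = list(exposed = w_exp, unexposed = w_une),
       corrected = pleiotropyCorrect(w_exp, w_une),
       n_dropped = strata$n_dropped)
}

#' Positive and negative control regressions
#'
#' Regresses each control phenotype on the instrument within each
#' maternal-smoking stratum: birthweight (the positive control -- the
#' instrument should associate negatively in the exposed stratum only) with
#' linear regression, and binary/continuous negative-control covariates
#' (which should be null everywhere under exchangeability) with
#' logistic/linear regression as appropriate.
#'
#' @param cohort an \code{\linkS4class{MRCohort}}.
#' @param instrument SNP id or numeric per-offspring vector.
#' @param controls named character vector mapping control column ->
#'   "linear" or "logistic"; defaults cover birthweight and the standard
#'   covariate set.
#' @param covariates optional adjustment columns (e.g. principal
#'   components).
#' @return tidy \code{data.frame}: control, stratum, family, beta, se,
#'   ci_low, ci_high, p, n.
#' @export
controlChecks <- function(cohort, instrument,
                          controls = c(birthweight_kg = "linear",
                                       sex = "logistic",
                                       multiple_birth = "logistic",
                                       breastfed = "logistic",
                                       birth_year = "linear",
                                       townsend = "linear"),
                          covariates = NULL) {
  inst <- .resolveInstrument(cohort, instrument)
  strata <- stratifyCohort(cohort)
  sm <- phenotypes(cohort)$maternal_smoked
  keep <- list(exposed = !is.na(sm) & sm == 1,
               unexposed = !is.na(sm) & sm == 0)
  rows <- list()
  for (ctl in names(controls)) {
    for (st in c("exposed", "unexposed")) {
      a <- geneticAssociation(strata[[st]], inst$values[keep[[st]]],
                              outcome = ctl, covariates = covariates,
                              family = controls[[ctl]], stratum = st,
                              instrument_label = inst$label)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(control = ctl, stringsAsFactors = FALSE),
              as.data.frame(a))
    }
  }
  do.call(rbind, rows)
}
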