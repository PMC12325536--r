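## Monte-Carlo evaluation of the proxy GxE design: power, bias and coverage
## over replicated synthetic cohorts, the proxy-attenuation experiment, and
## reproducible collider-bias demonstrations.

#' Define a power-simulation scenario
#'
#' Bundles base simulation parameters with a grid of causal effect sizes
#' (odds ratios of left-handedness per SD of cigarettes/day), a replicate
#' count, the test level and the estimator to evaluate.
#'
#' @param sim a \code{\linkS4class{SimParams}} (its \code{causal_beta} is
#'   overridden by the grid).
#' @param effect_grid causal odds ratios per SD of cigarettes/day (> 0);
#'   1 is the null.
#' @param n_replicates Monte-Carlo replicates per grid point (>= 1).
#' @param alpha test level in (0, 1).
#' @param estimator "corrected" (pleiotropy-corrected difference) or
#'   "exposed" (exposed-stratum Wald estimate).
#' @return a list of class \code{"PowerScenario"}.
#' @export
powerScenario <- function(sim = simParams(), effect_grid = c(1, 1.2, 1.44),
                          n_replicates = 200, alpha = 0.05,
                          estimator = c("corrected", "exposed")) {
  estimator <- match.arg(estimator)
  stopifnot(n_replicates >= 1, alpha > 0, alpha < 1, all(effect_grid > 0))
  structure(list(sim = sim, effect_grid = effect_grid,
                 n_replicates = n_replicates, alpha = alpha,
                 estimator = estimator),
            class = "PowerScenario")
}

## SD of cigarettes/day among smokers implied by the parameters (truncation
## at zero ignored; negligible at the default mean/sd).
.exposureSD <- function(params) {
  var_g <- sum(params@snp_weights^2 *
                 2 * params@allele_freqs * (1 - params@allele_freqs))
  sqrt(params@exposure_sd^2 + var_g)
}

## One replicate of the full pipeline on the weighted-dosage instrument;
## returns the chosen estimator on the per-cigarette log-odds scale.
.oneReplicate <- function(params, estimator) {
  coh <- generateCohort(params)
  inst <- drop(crossprod(offspringDosage(coh), params@snp_weights))
  fit <- proxyMR(coh, inst, instrument_label = "score")
  est <- if (estimator == "corrected") {
    c(beta = fit$corrected@beta_corrected, se = fit$corrected@se)
  } else {
    c(beta = fit$wald$exposed@beta_iv, se = fit$wald$exposed@se_iv)
  }
  est
}

#' Monte-Carlo power, bias and coverage of the proxy GxE estimators
#'
#' For each causal odds ratio in the grid, the per-SD effect is converted to
#' a per-cigarette log-odds (\code{log(OR) / sd(cigs/day)}), cohorts are
#' simulated, the full stratified Wald-ratio pipeline is run, and the
#' rejection rate at level alpha, mean estimate, bias and 95\% CI coverage
#' of the truth are recorded. Replicate seeds are derived from
#' \code{master_seed}; failed replicates are counted, not fatal.
#'
#' @param scenario a \code{\link{powerScenario}}.
#' @param master_seed integer seed for the whole run.
#' @return \code{data.frame} with one row per grid point: \code{effect_or},
#'   \code{true_beta} (per cigarette/day), \code{power},
#'   \code{mean_estimate}, \code{bias}, \code{coverage}, \code{mc_se},
#'   \code{n_replicates}, \code{n_failed}.
#' @export
runPowerScenario <- function(scenario, master_seed = 1L) {
  stopifnot(inherits(scenario, "PowerScenario"))
  sd_cigs <- .exposureSD(scenario$sim)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max,
                      scenario$n_replicates * length(scenario$effect_grid))
  dim(seeds) <- c(scenario$n_replicates, length(scenario$effect_grid))
  zcrit <- qnorm(1 - scenario$alpha / 2)
  out <- lapply(seq_along(scenario$effect_grid), function(g) {
    or_sd <- scenario$effect_grid[g]
    beta_cig <- log(or_sd) / sd_cigs
    ests <- matrix(NA_real_, scenario$n_replicates, 2)
    for (r in seq_len(scenario$n_replicates)) {
      params <- scenario$sim
      params@causal_beta <- beta_cig
      params@seed <- seeds[r, g]
      res <- tryCatch(suppressWarnings(
        .oneReplicate(params, scenario$estimator)),
        error = function(e) c(beta = NA_real_, se = NA_real_))
      ests[r, ] <- res
    }
    ok <- complete.cases(ests)
    beta <- ests[ok, 1]; se <- ests[ok, 2]
    power <- mean(abs(beta / se) > zcrit)
    cover <- mean(abs(beta - beta_cig) <= Z975 * se)
    data.frame(effect_or = or_sd, true_beta = beta_cig,
               power = power, mean_estimate = mean(beta),
               bias = mean(beta) - beta_cig, coverage = cover,
               mc_se = sqrt(power * (1 - power) / sum(ok)),
               n_replicates = scenario$n_replicates,
               n_failed = sum(!ok))
  })
  do.call(rbind, out)
}

#' Proxy attenuation of the instrument--exposure R-squared
#'
#' Simulates mother--father--offspring genotype trios under HWE and
#' Mendelian transmission, generates a maternal quantitative exposure as a
#' dosage effect plus Gaussian noise, and returns the ratio
#' \code{R2(exposure ~ offspring dosage) / R2(exposure ~ maternal dosage)}.
#' Under random mating this ratio is 1/4 -- the offspring genotype, as a
#' proxy for the maternal genotype, recovers only ~25\% of the variance the
#' maternal genotype explains; positive spousal correlation \code{s} raises
#' it to \code{(1 + s)^2 / (2 * (2 + s))} (the squared mother--offspring
#' dosage correlation under the generator's spousal-copying model).
#'
#' @param params a \code{\linkS4class{SimParams}}; \code{allele_freqs},
#'   \code{snp_weights}, \code{exposure_sd} and \code{spousal_cor} are used.
#' @param n number of trios (overrides \code{params@n_pairs}).
#' @param seed integer seed.
#' @return list with \code{ratio}, \code{r2_maternal}, \code{r2_offspring}.
#' @examples
#' proxyAttenuation(simParams(), n = 20000, seed = 1)$ratio  # ~0.25
#' @export
proxyAttenuation <- function(params = simParams(), n = 200000,
                             seed = params@seed) {
  set.seed(seed)
  g <- drawParentalGenotypes(params@allele_freqs, n,
                             spousal_cor = params@spousal_cor)
  off <- transmitGenotypes(g$maternal, g$paternal)
  # latent heaviness for every mother (no initiation gate, no truncation:
  # this experiment isolates the genetic attenuation)
  expo <- drop(g$maternal$dosage %*% params@snp_weights) +
    rnorm(n, 0, params@exposure_sd)
  score_m <- drop(g$maternal$dosage %*% params@snp_weights)
  score_o <- drop(off %*% params@snp_weights)
  r2_m <- as.numeric(varianceExplained(score_m, expo))
  r2_o <- as.numeric(varianceExplained(score_o, expo))
  if (is.na(r2_m) || is.na(r2_o) || r2_m == 0)
    stop("degenerate variance in the attenuation experiment", call. = FALSE)
  list(ratio = r2_o / r2_m, r2_maternal = r2_m, r2_offspring = r2_o)
}

.assocRow <- function(fit, term, analysis, stratum, n) {
  sm <- summary(fit)$coefficients
  est <- sm[term, 1]; se <- sm[term, 2]
  data.frame(analysis = analysis, stratum = stratum, term = term,
             estimate = est, se = se,
             ci_low = est - Z975 * se, ci_high = est + Z975 * se,
             p = sm[term, 4], n = n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Collider-bias demonstrations
#'
#' Two reproducible demonstrations on a synthetic cohort:
#' \itemize{
#'   \item \code{"initiation"}: when the instrument influences smoking
#'     initiation and a confounder U influences both initiation and
#'     handedness, stratifying on smoking status makes initiation a
#'     collider -- the instrument is independent of U marginally but
#'     associated with U within each smoking stratum. Reports the
#'     instrument--confounder regression marginally and per stratum.
#'   \item \code{"birthweight"}: when maternal smoking lowers birthweight
#'     and U influences both birthweight and handedness, adjusting for
#'     birthweight makes it a collider -- the smoking--handedness odds ratio
#'     moves away from its crude value. Reports the maternal-smoking
#'     log-odds ratio crude and birthweight-adjusted.
#' }
#'
#' @param params a \code{\linkS4class{SimParams}} encoding the scenario's
#'   open paths (see \code{\link{colliderParams}} for presets).
#' @param n cohort size (overrides \code{params@n_pairs}).
#' @param seed integer seed.
#' @return tidy \code{data.frame}: analysis, stratum, term, estimate, se,
#'   ci_low, ci_high, p, n.
#' @export
colliderDemo <- function(params, n = params@n_pairs, seed = params@seed) {
  params@n_pairs <- n
  params@seed <- as.integer(seed)
  coh <- generateCohort(params)
  ph <- phenotypes(coh)
  inst <- as.numeric(offspringDosage(coh)[1, ])
  rows <- list()
  # instrument-confounder: marginal, then within smoking strata
  d <- data.frame(U = ph$confounder, inst = inst, sm = ph$maternal_smoked,
                  left = ph$left_handed, bw = ph$birthweight_kg)
  rows[[1]] <- .assocRow(lm(U ~ inst, data = d), "inst",
                         "instrument_confounder", "marginal", nrow(d))
  rows[[2]] <- .assocRow(lm(U ~ inst, data = d, subset = sm == 1), "inst",
                         "instrument_confounder", "exposed", sum(d$sm == 1))
  rows[[3]] <- .assocRow(lm(U ~ inst, data = d, subset = sm == 0), "inst",
                         "instrument_confounder", "unexposed",
                         sum(d$sm == 0))
  # smoking-handedness: crude, then conditioning on birthweight
  crude <- glm(left ~ sm, data = d, family = binomial())
  adj <- glm(left ~ sm + bw, data = d, family = binomial())
  rows[[4]] <- .assocRow(crude, "sm", "smoking_handedness", "crude", nrow(d))
  rows[[5]] <- .assocRow(adj, "sm", "smoking_handedness",
                         "birthweight_adjusted", nrow(d))
  do.call(rbind, rows)
}

#' Preset parameters for the collider scenarios
#'
#' \code{"initiation"} opens the genotype-to-initiation and
#' confounder-to-initiation/handedness paths (smoking status becomes a
#' collider under stratification); \code{"birthweight"} opens the
#' smoking-to-birthweight and confounder-to-birthweight/handedness paths
#' (birthweight becomes a collider under adjustment). Both keep the causal
#' smoking-to-handedness path closed so any association seen is pure
#' collider bias.
#'
#' @param scenario "initiation" or "birthweight".
#' @param n_pairs,seed forwarded to \code{\link{simParams}}.
#' @return a \code{\linkS4class{SimParams}}.
#' @export
colliderParams <- function(scenario = c("initiation", "birthweight"),
                           n_pairs = 50000, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "initiation") {
    simParams(n_pairs = n_pairs, seed = seed,
              init_per_allele = 0.4, conf_on_init = 0.8,
              conf_on_outcome = 0.5)
  } else {
    simParams(n_pairs = n_pairs, seed = seed,
              bw_theta = -0.025, conf_on_birthweight = 0.3,
              conf_on_outcome = 0.5)
  }
}
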