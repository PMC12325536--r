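## Traditional observational stage: univariable / multivariable logistic
## regression of handedness on early-life predictors, with the cohort's
## encodings (seasonal cosine for birth month, z-scored Townsend, dummy-coded
## country against England) and McFadden pseudo R^2.

#' Seasonal cosine encoding of birth month
#'
#' Maps month of birth to \code{cos(pi * (month - 6.5) / 3)}: a smooth
#' seasonal covariate in [-1, 1] with period 6 months, peaking in the UK
#' summer (June/July) and winter (December/January) and dipping in
#' spring/autumn, so adjacent months are more alike than distant ones.
#'
#' @param month integer vector with values in 1..12.
#' @return numeric vector in [-1, 1].
#' @examples
#' encodeMonth(6)   #  0.866
#' encodeMonth(3)   # -0.866
#' @export
encodeMonth <- function(month) {
  ok <- is.na(month) | (month %in% 1:12)
  if (!all(ok))
    stop("'month' must be an integer in 1..12", call. = FALSE)
  cos(pi * (month - 6.5) / 3)
}

#' Declare how a predictor enters the handedness models
#'
#' A \code{PredictorSpec} names a column, its role (binary, categorical or
#' continuous), the reference level for dummy coding, and an optional
#' transform: \code{"seasonal-cosine"} (\code{\link{encodeMonth}}) or
#' \code{"z-score"}.
#'
#' @param name column name in the cohort table.
#' @param role one of "binary", "categorical", "continuous".
#' @param reference_level reference category for categorical predictors.
#' @param transform one of "none", "seasonal-cosine", "z-score".
#' @return a one-row \code{data.frame} with class \code{"PredictorSpec"}
#'   rows; combine several with \code{rbind}.
#' @export
predictorSpec <- function(name, role = c("continuous", "binary",
                                         "categorical"),
                          reference_level = NA_character_,
                          transform = c("none", "seasonal-cosine",
                                        "z-score")) {
  role <- match.arg(role)
  transform <- match.arg(transform)
  data.frame(name = name, role = role, reference_level = reference_level,
             transform = transform, stringsAsFactors = FALSE)
}

#' Default predictor specifications for the handedness analysis
#'
#' The standard early-life predictor set: sex, multiple birth, maternal
#' smoking in pregnancy, breastfeeding, country of origin (reference
#' England), birth year, birthweight, seasonal-cosine birth month and
#' z-scored Townsend deprivation.
#'
#' @return a \code{data.frame} of predictor specifications.
#' @export
defaultPredictorSpecs <- function() {
  rbind(
    predictorSpec("sex", "binary"),
    predictorSpec("multiple_birth", "binary"),
    predictorSpec("maternal_smoked", "binary"),
    predictorSpec("breastfed", "binary"),
    predictorSpec("country", "categorical", reference_level = "England"),
    predictorSpec("birth_year", "continuous"),
    predictorSpec("birthweight_kg", "continuous"),
    predictorSpec("birth_month", "continuous",
                  transform = "seasonal-cosine"),
    predictorSpec("townsend", "continuous", transform = "z-score"))
}

## Apply a PredictorSpec table to a data.frame, returning the encoded design
## columns (still a data.frame; factors carry their reference level).
.encodePredictors <- function(data, specs) {
  out <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (!s$name %in% colnames(data))
      stop("predictor '", s$name, "' not found in data", call. = FALSE)
    x <- data[[s$name]]
    if (s$transform == "seasonal-cosine") x <- encodeMonth(x)
    if (s$transform == "z-score") x <- as.numeric(scale(x))
    if (s$role == "categorical") {
      x <- as.factor(x)
      if (!is.na(s$reference_level)) {
        if (!s$reference_level %in% levels(x))
          stop("reference level '", s$reference_level,
               "' absent from '", s$name, "'", call. = FALSE)
        x <- stats::relevel(x, ref = s$reference_level)
      }
    }
    if (s$role == "binary" && !is.numeric(x)) x <- as.factor(x)
    out[[s$name]] <- x
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.tidyGlmTerms <- function(fit, n_used, flagged = FALSE,
                          flag_reason = NA_character_) {
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  keep <- terms != "(Intercept)"
  est <- sm[keep, 1]; se <- sm[keep, 2]; p <- sm[keep, 4]
  data.frame(term = terms[keep], estimate = est, se = se,
             odds_ratio = exp(est),
             ci_low = exp(est - Z975 * se), ci_high = exp(est + Z975 * se),
             p_value = p, n_used = n_used, flagged = flagged,
             flag_reason = flag_reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Separation / non-convergence heuristics: glm's own convergence flag, a
## fitted probability numerically at 0/1, or an absurd Wald SE.
.logisticFlags <- function(fit) {
  eps <- 10 * .Machine$double.eps
  if (!fit$converged) return("did not converge")
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps))
    return("possible separation: fitted probabilities at 0 or 1")
  if (any(summary(fit)$coefficients[, 2] > 100))
    return("possible separation: unstable standard errors")
  NA_character_
}

#' Univariable or prespecified logistic regression of a binary outcome
#'
#' Maximum-likelihood logistic fit of \code{outcome} on the encoded columns
#' of \code{design}, on complete cases only. Each non-intercept term is
#' reported as an odds ratio with a 95\% Wald CI and a two-sided Wald p.
#' Separation and non-convergence are flagged in the result (columns
#' \code{flagged}, \code{flag_reason}), never silently ignored; a
#' rank-deficient design is an error naming the collinear terms.
#'
#' @param outcome binary (0/1 or two-level) vector.
#' @param design \code{data.frame} of encoded predictors.
#' @return a \code{data.frame} with one row per model term: \code{term},
#'   \code{estimate} (log-odds), \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{n_used}, flag columns.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200))
#' y <- rbinom(200, 1, plogis(-1 + d$x))
#' fitLogistic(y, d)
#' @export
fitLogistic <- function(outcome, design) {
  design <- as.data.frame(design)
  if (is.factor(outcome) || is.character(outcome)) {
    lv <- sort(unique(as.character(outcome[!is.na(outcome)])))
    if (length(lv) != 2)
      stop("'outcome' must have exactly two levels", call. = FALSE)
    outcome <- as.integer(as.character(outcome) == lv[2])
  }
  cc <- complete.cases(design) & !is.na(outcome)
  if (!any(cc)) stop("no complete cases", call. = FALSE)
  df <- design[cc, , drop = FALSE]
  df$.y <- outcome[cc]
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reason <- .logisticFlags(fit)
  .tidyGlmTerms(fit, sum(cc), flagged = !is.na(reason), flag_reason = reason)
}

#' Univariable scan over a predictor specification table
#'
#' Fits one logistic regression of the outcome per predictor, each encoded
#' per its \code{\link{predictorSpec}}, and stacks the per-term results with
#' a \code{model_id} column naming the predictor.
#'
#' @param data cohort \code{data.frame} (e.g. \code{phenotypes(cohort)}).
#' @param specs predictor specification table.
#' @param outcome name of the binary outcome column.
#' @return stacked results \code{data.frame}.
#' @export
univariableScan <- function(data, specs = defaultPredictorSpecs(),
                            outcome = "left_handed") {
  res <- lapply(seq_len(nrow(specs)), function(i) {
    enc <- .encodePredictors(data, specs[i, , drop = FALSE])
    r <- fitLogistic(data[[outcome]], enc)
    r$model_id <- specs$name[i]
    r
  })
  do.call(rbind, res)
}

#' Multivariable logistic regression with McFadden pseudo R-squared
#'
#' Single joint logistic fit of the outcome on all specified predictors
#' (plus optional precomputed principal-component covariates), on complete
#' cases across every predictor. Reports McFadden's pseudo R^2
#' = 1 - logLik(model) / logLik(null), the null being an intercept-only fit
#' on the same rows.
#'
#' @param data cohort \code{data.frame}.
#' @param specs predictor specification table.
#' @param outcome name of the binary outcome column.
#' @param pcs optional \code{data.frame}/matrix of principal-component
#'   covariates (aligned to \code{data} rows) to adjust for.
#' @return a list with \code{results} (per-term \code{data.frame}),
#'   \code{pseudo_r2} and \code{n_used}.
#' @export
multivariableFit <- function(data, specs = defaultPredictorSpecs(),
                             outcome = "left_handed", pcs = NULL) {
  design <- .encodePredictors(data, specs)
  if (!is.null(pcs)) {
    pcs <- as.data.frame(pcs)
    if (nrow(pcs) != nrow(design))
      stop("'pcs' must have one row per cohort row", call. = FALSE)
    design <- cbind(design, pcs)
  }
  cc <- complete.cases(design) & !is.na(data[[outcome]])
  if (!any(cc)) stop("no complete cases across the predictor set",
                     call. = FALSE)
  res <- fitLogistic(data[[outcome]][cc], design[cc, , drop = FALSE])
  df <- design[cc, , drop = FALSE]
  df$.y <- if (is.numeric(data[[outcome]])) data[[outcome]][cc] else
    as.integer(as.factor(data[[outcome]][cc])) - 1L
  full <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  null <- glm(.y ~ 1, data = df, family = binomial())
  list(results = res, pseudo_r2 = mcfaddenR2(logLik(full), logLik(null)),
       n_used = sum(cc))
}

#' McFadden pseudo R-squared
#'
#' \code{1 - ll_model / ll_null} for log-likelihoods of a fitted and an
#' intercept-only discrete-outcome model on the same rows.
#'
#' @param ll_model,ll_null log-likelihoods (numeric or \code{logLik}).
#' @return pseudo R^2 in [0, 1).
#' @examples
#' mcfaddenR2(-50, -100)  # 0.5
#' @export
mcfaddenR2 <- function(ll_model, ll_null) {
  1 - as.numeric(ll_model) / as.numeric(ll_null)
}

#' Pairwise association between two cohort variables
#'
#' Dispatches on variable roles: Cramer's V
#' (\code{sqrt(chisq / (n * (min(r, c) - 1)))}, chi-square without continuity
#' correction) for two categorical variables, Pearson's correlation for two
#' continuous variables, and Spearman's rho for a mixed pair. Complete cases
#' only; a constant variable yields \code{NA} with a reason rather than an
#' error.
#'
#' @param x,y vectors of equal length.
#' @param x_role,y_role "auto" (default: factors/characters/logicals and
#'   numerics with few distinct values are categorical), "categorical" or
#'   "continuous".
#' @return a one-row \code{data.frame}: \code{measure}, \code{measure_type}
#'   ("cramers_v", "pearson" or "spearman"), \code{n}, \code{reason}.
#' @examples
#' pairwiseAssociation(c(rep("a", 20), rep("b", 20)),
#'                     rep(c("x", "y"), 20))
#' @export
pairwiseAssociation <- function(x, y, x_role = "auto", y_role = "auto") {
  guess <- function(v, role) {
    if (role != "auto") return(role)
    if (is.factor(v) || is.character(v) || is.logical(v)) "categorical"
    else if (length(unique(v[!is.na(v)])) <= 2) "categorical"
    else "continuous"
  }
  rx <- guess(x, x_role); ry <- guess(y, y_role)
  cc <- !is.na(x) & !is.na(y)
  x <- x[cc]; y <- y[cc]; n <- sum(cc)
  res <- function(measure, type, reason = NA_character_)
    data.frame(measure = measure, measure_type = type, n = n,
               reason = reason, stringsAsFactors = FALSE)
  type <- if (rx == "categorical" && ry == "categorical") "cramers_v"
          else if (rx == "continuous" && ry == "continuous") "pearson"
          else "spearman"
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(res(NA_real_, type, "constant variable on complete cases"))
  if (type == "cramers_v") {
    tab <- table(x, y)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
    v <- sqrt(as.numeric(chi) / (n * (min(dim(tab)) - 1)))
    return(res(v, type))
  }
  if (type == "pearson") return(res(cor(x, y), type))
  if (rx == "categorical") x <- as.numeric(as.factor(x))
  if (ry == "categorical") y <- as.numeric(as.factor(y))
  res(cor(x, y, method = "spearman"), type)
}

#' Pairwise association matrix over a variable set
#'
#' Applies \code{\link{pairwiseAssociation}} to every unordered pair of the
#' named columns.
#'
#' @param data cohort \code{data.frame}.
#' @param vars column names.
#' @return long-format \code{data.frame} with \code{var1}, \code{var2},
#'   \code{measure}, \code{measure_type}, \code{n}.
#' @export
associationMatrix <- function(data, vars) {
  pairs <- utils::combn(vars, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- pairwiseAssociation(data[[a]], data[[b]])
    cbind(data.frame(var1 = a, var2 = b, stringsAsFactors = FALSE), r)
  })
  do.call(rbind, out)
}
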