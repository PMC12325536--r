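## Synthetic mother-father-offspring cohort generator.
## Parental genotypes are drawn allele-wise under HWE so that Mendelian
## transmission can sample one allele per parent; haplotypes are retained so
## tests can verify transmission directly.

#' Draw parental genotypes under Hardy--Weinberg equilibrium
#'
#' Each parent's two alleles are independent Bernoulli(freq) draws per SNP
#' (dosage = allele sum), so genotype classes follow (1-p)^2, 2p(1-p), p^2.
#' With \code{spousal_cor = s > 0}, each paternal allele is, with
#' probability s, identical by state to the mother's corresponding allele at
#' that SNP, which makes the maternal--paternal dosage correlation exactly
#' s while preserving each parent's HWE marginal. Under Mendelian
#' transmission this gives corr(offspring, maternal dosage)
#' = (1+s)/sqrt(2(2+s)) (0.5 at s = 0); random mating is the default.
#'
#' @param freqs per-SNP effect-allele frequencies, strictly in (0,1).
#' @param n number of couples.
#' @param seed optional integer seed.
#' @param spousal_cor maternal--paternal dosage correlation in [0,1).
#' @return a list with elements \code{maternal} and \code{paternal}, each a
#'   list of \code{h1}, \code{h2} (n x SNP 0/1 haplotype matrices) and
#'   \code{dosage} (their sum).
#' @examples
#' g <- drawParentalGenotypes(0.5, 1000, seed = 1)
#' mean(g$maternal$dosage)  # ~ 1
#' @export
drawParentalGenotypes <- function(freqs, n, seed = NULL, spousal_cor = 0) {
  if (any(!is.finite(freqs)) || any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  if (spousal_cor < 0 || spousal_cor >= 1)
    stop("'spousal_cor' must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- length(freqs)
  drawHap <- function() matrix(rbinom(n * m, 1L, rep(freqs, each = n)),
                               nrow = n, ncol = m)
  mat <- list(h1 = drawHap(), h2 = drawHap())
  pat <- list(h1 = drawHap(), h2 = drawHap())
  if (spousal_cor > 0 && n > 0) {
    # copy the *matching* haplotype so the father's two alleles stay
    # independent (keeps HWE) and corr(paternal, maternal dosage) = s
    for (h in c("h1", "h2")) {
      copy <- matrix(runif(n * m) < spousal_cor, nrow = n, ncol = m)
      pat[[h]][copy] <- mat[[h]][copy]
    }
  }
  mat$dosage <- mat$h1 + mat$h2
  pat$dosage <- pat$h1 + pat$h2
  snp_ids <- paste0("snp", seq_len(m))
  for (p in c("h1", "h2", "dosage")) {
    colnames(mat[[p]]) <- snp_ids
    colnames(pat[[p]]) <- snp_ids
  }
  list(maternal = mat, paternal = pat)
}

#' Mendelian transmission of parental haplotypes to offspring
#'
#' One allele is sampled uniformly from each parent's pair at every SNP, so
#' the offspring dosage is in {0,1,2}, is always Mendelian-consistent with
#' the parental pairs, and correlates 0.5 with each parent's dosage under
#' random mating.
#'
#' @param maternal,paternal haplotype lists as returned by
#'   \code{\link{drawParentalGenotypes}} (elements \code{h1}, \code{h2}).
#' @param seed optional integer seed.
#' @return offspring dosage matrix (n x SNP).
#' @export
transmitGenotypes <- function(maternal, paternal, seed = NULL) {
  dm <- dim(maternal$h1)
  if (is.null(dm) || !identical(dm, dim(paternal$h1)) ||
      !identical(dm, dim(maternal$h2)) || !identical(dm, dim(paternal$h2)))
    stop("parental haplotype matrices must share the same dimensions",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fromMat <- matrix(runif(prod(dm)) < 0.5, dm[1], dm[2])
  fromPat <- matrix(runif(prod(dm)) < 0.5, dm[1], dm[2])
  off <- ifelse(fromMat, maternal$h1, maternal$h2) +
    ifelse(fromPat, paternal$h1, paternal$h2)
  colnames(off) <- colnames(maternal$h1)
  off
}

#' Simulate maternal smoking initiation and heaviness
#'
#' Smoking status in pregnancy is Bernoulli on the logit scale:
#' \code{logit(init_base) + init_per_allele * (maternal allele count) +
#' conf_on_init * U}. Among smokers, cigarettes/day is
#' \code{exposure_mean + sum(snp_weights * maternal dosage)} plus Gaussian
#' noise with SD \code{exposure_sd}, truncated at zero; non-smokers have
#' \code{cigs_per_day = NA}.
#'
#' @param maternal_dosage n x SNP maternal dosage matrix.
#' @param U latent confounder vector (length n).
#' @param params a \code{\linkS4class{SimParams}}.
#' @param seed optional integer seed.
#' @return list with \code{maternal_smoked} (0/1) and \code{cigs_per_day}
#'   (NA for non-smokers).
#' @export
simulateExposure <- function(maternal_dosage, U, params, seed = NULL) {
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  maternal_dosage <- as.matrix(maternal_dosage)
  n <- nrow(maternal_dosage)
  if (length(U) != n)
    stop("'U' must have one value per mother", call. = FALSE)
  allele_count <- rowSums(maternal_dosage)
  lin <- qlogis(params@init_base) + params@init_per_allele * allele_count +
    params@conf_on_init * U
  smoked <- rbinom(n, 1L, plogis(lin))
  genetic <- drop(maternal_dosage %*% params@snp_weights)
  cigs <- params@exposure_mean + genetic + rnorm(n, 0, params@exposure_sd)
  cigs <- pmax(cigs, 0)
  cigs[smoked == 0] <- NA_real_
  list(maternal_smoked = smoked, cigs_per_day = cigs)
}

#' Simulate offspring handedness and birthweight
#'
#' Left-handedness is Bernoulli on the logit scale:
#' \code{outcome_base_logit + causal_beta * cigs_per_day * maternal_smoked +
#' pleiotropy_beta * (offspring allele count) + conf_on_outcome * U}. The
#' causal path acts only through cigarettes actually smoked; the pleiotropic
#' path acts through the offspring genome regardless of maternal smoking.
#' Birthweight is the negative-control outcome:
#' \code{bw_base + bw_theta * cigs_per_day * maternal_smoked +
#' conf_on_birthweight * U} plus Gaussian noise, floored at 0.2 kg.
#'
#' @param offspring_dosage n x SNP offspring dosage matrix.
#' @param maternal_smoked,cigs_per_day exposure fields from
#'   \code{\link{simulateExposure}}.
#' @param U latent confounder vector.
#' @param params a \code{\linkS4class{SimParams}}.
#' @param seed optional integer seed.
#' @return list with \code{left_handed} (0/1) and \code{birthweight_kg}.
#' @export
simulateOutcomes <- function(offspring_dosage, maternal_smoked, cigs_per_day,
                             U, params, seed = NULL) {
  validObject(params)
  if (is.null(maternal_smoked) || is.null(cigs_per_day))
    stop("exposure fields must be simulated before outcomes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  offspring_dosage <- as.matrix(offspring_dosage)
  n <- nrow(offspring_dosage)
  dose_cigs <- ifelse(maternal_smoked == 1, cigs_per_day, 0)
  lin <- params@outcome_base_logit + params@causal_beta * dose_cigs +
    params@pleiotropy_beta * rowSums(offspring_dosage) +
    params@conf_on_outcome * U
  left <- rbinom(n, 1L, plogis(lin))
  bw <- params@bw_base + params@bw_theta * dose_cigs +
    params@conf_on_birthweight * U + rnorm(n, 0, params@bw_sd)
  list(left_handed = left, birthweight_kg = pmax(bw, 0.2))
}

## Covariate marginals follow the UK-Biobank baseline table: 54.5% female,
## 2.25% multiple births, 71.2% breastfed, birth years centred on 1951,
## Townsend mean -1.53 (z-score; the cohort is less deprived than the
## national average).
.covariateMarginals <- list(
  p_female = 0.545,
  p_multiple = 0.0225,
  p_breastfed = 0.7121,
  birth_years = 1936:1966,
  countries = c(England = 0.8424, Wales = 0.0479, Scotland = 0.0858,
                `Northern Ireland` = 0.0049, `Republic of Ireland` = 0.0006,
                Elsewhere = 0.0184),
  townsend_mean = -1.53,
  townsend_sd = 3)

.simulateCovariates <- function(n) {
  mg <- .covariateMarginals
  data.frame(
    sex = ifelse(runif(n) < mg$p_female, "female", "male"),
    multiple_birth = as.integer(runif(n) < mg$p_multiple),
    breastfed = as.integer(runif(n) < mg$p_breastfed),
    birth_year = if (n) sample(mg$birth_years, n, replace = TRUE)
                 else integer(0),
    birth_month = if (n) sample(1:12, n, replace = TRUE) else integer(0),
    country = if (n) sample(names(mg$countries), n, replace = TRUE,
                            prob = mg$countries) else character(0),
    townsend = rnorm(n, mg$townsend_mean, mg$townsend_sd),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic mother--offspring cohort
#'
#' Composes \code{\link{drawParentalGenotypes}},
#' \code{\link{transmitGenotypes}}, \code{\link{simulateExposure}} and
#' \code{\link{simulateOutcomes}} with independently drawn early-life
#' covariates into a fully populated \code{\linkS4class{MRCohort}}. The
#' latent confounder U is retained in \code{colData} (column
#' \code{confounder}) for oracle checks, as are the latent maternal and
#' paternal dosage assays. Output is bit-identical for identical
#' (params, seed).
#'
#' @param params a \code{\linkS4class{SimParams}}; its \code{seed} slot
#'   drives all randomness.
#' @return an \code{\linkS4class{MRCohort}}.
#' @examples
#' coh <- generateCohort(simParams(n_pairs = 500, seed = 42))
#' coh
#' @export
generateCohort <- function(params) {
  validObject(params)
  n <- as.integer(params@n_pairs)
  set.seed(params@seed)
  g <- drawParentalGenotypes(params@allele_freqs, n,
                             spousal_cor = params@spousal_cor)
  off <- transmitGenotypes(g$maternal, g$paternal)
  U <- rnorm(n, 0, params@confounder_sd)
  expo <- simulateExposure(g$maternal$dosage, U, params)
  out <- simulateOutcomes(off, expo$maternal_smoked, expo$cigs_per_day,
                          U, params)
  cov <- .simulateCovariates(n)
  cd <- S4Vectors::DataFrame(
    maternal_smoked = expo$maternal_smoked,
    cigs_per_day = expo$cigs_per_day,
    left_handed = out$left_handed,
    birthweight_kg = out$birthweight_kg,
    cov,
    confounder = U)
  m <- length(params@allele_freqs)
  snp_ids <- paste0("snp", seq_len(m))
  rd <- S4Vectors::DataFrame(
    snp_id = snp_ids,
    chrom = rep("1", m),
    pos = as.integer(seq_len(m) * 1e6),
    effect_allele = rep("A", m),
    other_allele = rep("G", m),
    allele_freq = params@allele_freqs,
    weight = params@snp_weights,
    row.names = snp_ids)
  sample_ids <- if (n) paste0("id", seq_len(n)) else character(0)
  rownames(cd) <- sample_ids
  toAssay <- function(x) {
    a <- t(x)
    dimnames(a) <- list(snp_ids, sample_ids)
    a
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(offspringDosage = toAssay(off),
                  maternalDosage = toAssay(g$maternal$dosage),
                  paternalDosage = toAssay(g$paternal$dosage)),
    rowData = rd, colData = cd,
    metadata = list(params = params))
  methods::new("MRCohort", se)
}

#' Write and read a cohort as tab-separated text
#'
#' \code{writeCohort} writes one row per offspring: all phenotype columns
#' followed by one offspring-dosage column per SNP (named by SNP id), with
#' \code{"NA"} for missing values. \code{readCohort} reads such a file back
#' into an \code{\linkS4class{MRCohort}}, treating every column named in
#' \code{snp_cols} (default: columns matching \code{"^snp"}) as a dosage.
#'
#' @param cohort an \code{\linkS4class{MRCohort}}.
#' @param file path to a TSV file.
#' @param snp_cols character vector of dosage column names, or \code{NULL}
#'   to auto-detect.
#' @return \code{readCohort} returns an \code{MRCohort};
#'   \code{writeCohort} returns \code{file} invisibly.
#' @export
writeCohort <- function(cohort, file) {
  df <- cbind(phenotypes(cohort),
              as.data.frame(t(offspringDosage(cohort))))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(file)
}

#' @rdname writeCohort
#' @export
readCohort <- function(file, snp_cols = NULL) {
  df <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA")
  if (is.null(snp_cols)) snp_cols <- grep("^snp", colnames(df), value = TRUE)
  if (!all(snp_cols %in% colnames(df)))
    stop("missing dosage columns: ",
         paste(setdiff(snp_cols, colnames(df)), collapse = ", "),
         call. = FALSE)
  dos <- t(as.matrix(df[, snp_cols, drop = FALSE]))
  ph <- df[, setdiff(colnames(df), snp_cols), drop = FALSE]
  n <- nrow(df)
  sample_ids <- if (n) paste0("id", seq_len(n)) else character(0)
  dimnames(dos) <- list(snp_cols, sample_ids)
  cd <- S4Vectors::DataFrame(ph, row.names = sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(offspringDosage = dos),
    rowData = S4Vectors::DataFrame(snp_id = snp_cols, row.names = snp_cols),
    colData = cd)
  methods::new("MRCohort", se)
}
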