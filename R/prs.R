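## Polygenic risk score construction: p-value thresholding, greedy LD
## clumping on a dosage panel, effect-allele harmonization, weighted scoring.

.PALINDROMES <- c("A/T", "T/A", "C/G", "G/C")

#' Greedy LD clumping of GWAS summary statistics
#'
#' PLINK-style clumping: SNPs passing the p-value threshold are taken as
#' index SNPs in ascending p order (ties broken by chromosome, position,
#' then SNP id); each index absorbs every remaining SNP on the same
#' chromosome within \code{window_kb} kilobases whose squared Pearson
#' correlation of dosages with the index exceeds \code{r2_thresh}. SNPs
#' above the p threshold never become indices and are never retained.
#' Defaults are genome-wide significance (p <= 5e-8), r^2 = 0.001 and a
#' 1000 kb window.
#'
#' r^2 is computed on the supplied dosage panel, so results are
#' panel-dependent; zero-variance panel columns are skipped with a warning.
#'
#' @param stats summary-statistics \code{data.frame} with columns
#'   \code{snp_id}, \code{chrom}, \code{pos}, \code{p} (see
#'   \code{\link{readSumstats}}).
#' @param panel numeric dosage matrix, individuals x SNPs, with column names
#'   covering every SNP in \code{stats}.
#' @param p_thresh,r2_thresh,window_kb clumping thresholds.
#' @return a \code{\linkS4class{ClumpResult}}.
#' @examples
#' stats <- data.frame(snp_id = c("a", "b"), chrom = "1",
#'                     pos = c(100L, 5100L), p = c(1e-10, 1e-9))
#' panel <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 1, 2))
#' clumpVariants(stats, panel, r2_thresh = 0.5, window_kb = 10)
#' @export
clumpVariants <- function(stats, panel, p_thresh = 5e-8, r2_thresh = 0.001,
                          window_kb = 1000) {
  stats <- as.data.frame(stats)
  panel <- as.matrix(panel)
  if (nrow(stats) == 0)
    return(new("ClumpResult", index_snps = character(0),
               removed = setNames(character(0), character(0)),
               skipped = character(0),
               params = list(p_thresh = p_thresh, r2_thresh = r2_thresh,
                             window_kb = window_kb)))
  missing <- setdiff(stats$snp_id, colnames(panel))
  if (length(missing))
    stop("SNP(s) absent from the dosage panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(panel) < 2)
    stop("dosage panel needs at least 2 individuals", call. = FALSE)
  vars <- apply(panel[, stats$snp_id, drop = FALSE], 2, var)
  skipped <- names(vars)[vars == 0]
  if (length(skipped))
    warning("skipping zero-variance SNP(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  cand <- stats[stats$p <= p_thresh & !(stats$snp_id %in% skipped), ,
                drop = FALSE]
  # deterministic ordering: p, then (chrom, pos, snp_id) for ties
  cand <- cand[order(cand$p, cand$chrom, cand$pos, cand$snp_id), ,
               drop = FALSE]
  index <- character(0)
  removed <- setNames(character(0), character(0))
  while (nrow(cand) > 0) {
    idx <- cand[1, ]
    index <- c(index, idx$snp_id)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    near <- cand$chrom == idx$chrom &
      abs(cand$pos - idx$pos) <= window_kb * 1000
    if (any(near)) {
      r2 <- cor(panel[, idx$snp_id],
                panel[, cand$snp_id[near], drop = FALSE])^2
      absorb <- cand$snp_id[near][drop(r2) > r2_thresh]
      if (length(absorb)) {
        removed <- c(removed, setNames(rep(idx$snp_id, length(absorb)),
                                       absorb))
        cand <- cand[!(cand$snp_id %in% absorb), , drop = FALSE]
      }
    }
  }
  new("ClumpResult", index_snps = index, removed = removed,
      skipped = skipped,
      params = list(p_thresh = p_thresh, r2_thresh = r2_thresh,
                    window_kb = window_kb))
}

#' Tidy report of a clumping result
#'
#' @param result a \code{\linkS4class{ClumpResult}}.
#' @param stats the summary statistics the result was computed from.
#' @return \code{data.frame} with one row per absorbed SNP: \code{index},
#'   \code{absorbed}, \code{distance_bp}.
#' @export
clumpReport <- function(result, stats) {
  if (!length(result@removed))
    return(data.frame(index = character(0), absorbed = character(0),
                      distance_bp = integer(0)))
  pos <- setNames(stats$pos, stats$snp_id)
  data.frame(index = unname(result@removed),
             absorbed = names(result@removed),
             distance_bp = abs(pos[names(result@removed)] -
                               pos[unname(result@removed)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Harmonize GWAS effect alleles with a genotype panel
#'
#' Aligns per-SNP effect sizes to the allele counted in the dosage panel:
#' if the counted allele equals the GWAS effect allele the weight is kept;
#' if it equals the other allele the weight's sign is flipped;
#' strand-ambiguous (A/T, C/G) and mismatched allele pairs are dropped and
#' reported, never fatal.
#'
#' @param stats summary statistics with \code{snp_id}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}.
#' @param panel_effect_alleles named character vector: counted allele per
#'   panel SNP.
#' @return list with \code{weights} (named numeric vector, aligned betas)
#'   and \code{dropped} (\code{data.frame} of snp_id + reason).
#' @export
harmonizeAlleles <- function(stats, panel_effect_alleles) {
  stats <- as.data.frame(stats)
  weights <- numeric(0)
  dropped <- list()
  for (i in seq_len(nrow(stats))) {
    s <- stats[i, ]
    pair <- paste(s$effect_allele, s$other_allele, sep = "/")
    if (pair %in% .PALINDROMES) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(snp_id = s$snp_id, reason = "strand-ambiguous (palindromic)")
      next
    }
    counted <- panel_effect_alleles[[s$snp_id]]
    if (is.null(counted) || is.na(counted)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(snp_id = s$snp_id, reason = "not present in panel")
      next
    }
    if (counted == s$effect_allele) {
      weights[s$snp_id] <- s$beta
    } else if (counted == s$other_allele) {
      weights[s$snp_id] <- -s$beta
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(snp_id = s$snp_id, reason = "allele mismatch")
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(snp_id = character(0), reason = character(0))
  list(weights = weights, dropped = dropped)
}

#' Compute a weighted polygenic risk score
#'
#' \code{score_i = sum_j weight_j * dosage_ij} over the weighted SNPs.
#' Missing dosages are imputed with the column mean (2 x allele frequency in
#' expectation). With \code{unweighted = TRUE} every weight's sign is kept
#' but its magnitude set to 1, giving the trait-increasing allele count used
#' in single-SNP analyses.
#'
#' @param dosages individuals x SNPs numeric matrix with column names.
#' @param weights named numeric vector; names must all be dosage columns.
#' @param unweighted count trait-increasing alleles instead of weighting.
#' @return numeric vector of per-individual scores.
#' @examples
#' computePRS(rbind(c(0, 1, 2)), setNames(c(0.1, -0.2, 0.3), c("a", "b", "c")))
#' @export
computePRS <- function(dosages, weights, unweighted = FALSE) {
  dosages <- as.matrix(dosages)
  if (is.null(names(weights)) || is.null(colnames(dosages)))
    stop("'weights' and dosage columns must both be named", call. = FALSE)
  missing <- setdiff(names(weights), colnames(dosages))
  if (length(missing))
    stop("weights name SNP(s) absent from the dosage matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- dosages[, names(weights), drop = FALSE]
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  w <- if (unweighted) sign(weights) else weights
  drop(d %*% w)
}

#' Variance in a phenotype explained by a score or dosage
#'
#' Squared Pearson correlation from the simple linear regression of the
#' phenotype on the predictor, on complete pairs. Degenerate inputs (fewer
#' than 3 complete pairs, or zero variance) return \code{NA} with a
#' \code{"reason"} attribute rather than an error.
#'
#' @param predictor,phenotype numeric vectors of equal length.
#' @return R^2 in [0, 1] (with attribute \code{"n"}), or \code{NA}.
#' @export
varianceExplained <- function(predictor, phenotype) {
  cc <- !is.na(predictor) & !is.na(phenotype)
  x <- predictor[cc]; y <- phenotype[cc]
  fail <- function(reason) structure(NA_real_, n = length(x), reason = reason)
  if (length(x) < 3) return(fail("fewer than 3 complete pairs"))
  if (var(x) == 0 || var(y) == 0) return(fail("zero variance"))
  structure(cor(x, y)^2, n = length(x))
}
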