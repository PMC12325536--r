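# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the logistic oracle maximises the likelihood by iterative
# grid refinement (no IRLS), and the clumping oracle is a naive loop with a
# hand-written r^2.

# Log-likelihood of a logistic model; X includes no intercept column (one is
# prepended here).
logisticLogLik <- function(beta, y, X) {
  eta <- cbind(1, X) %*% beta
  sum(y * eta - log1p(exp(eta)))
}

# Brute-force MLE by coarse-to-fine grid search over the coefficient vector
# (intercept + one column per predictor). Good to ~1e-4 after refinement.
logisticGridMLE <- function(y, X, half_width = 10, n_grid = 25,
                            n_refine = 8) {
  X <- as.matrix(X)
  d <- ncol(X) + 1L
  centre <- rep(0, d)
  width <- rep(half_width, d)
  for (it in seq_len(n_refine)) {
    axes <- lapply(seq_len(d), function(j)
      seq(centre[j] - width[j], centre[j] + width[j], length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    ll <- vapply(seq_len(nrow(grid)),
                 function(i) logisticLogLik(grid[i, ], y, X), numeric(1))
    centre <- grid[which.max(ll), ]
    width <- width * (2.5 / (n_grid - 1))  # keep neighbours inside next grid
  }
  centre
}

# Hand-rolled squared Pearson correlation.
r2Hand <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- (n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2)
  num^2 / den
}

# Naive reference clumping: explicit loops, hand-written r^2, no shared code
# with clumpVariants().
clumpOracle <- function(stats, panel, p_thresh, r2_thresh, window_kb) {
  keep <- rep(TRUE, nrow(stats))
  for (i in seq_len(nrow(stats))) {
    v <- panel[, stats$snp_id[i]]
    if (sum((v - mean(v))^2) == 0) keep[i] <- FALSE
    if (stats$p[i] > p_thresh) keep[i] <- FALSE
  }
  pool <- stats[keep, , drop = FALSE]
  index <- character(0)
  while (nrow(pool) > 0) {
    best <- 1L
    for (i in seq_len(nrow(pool))) {
      better <- pool$p[i] < pool$p[best] ||
        (pool$p[i] == pool$p[best] &&
           (pool$chrom[i] < pool$chrom[best] ||
              (pool$chrom[i] == pool$chrom[best] &&
                 (pool$pos[i] < pool$pos[best] ||
                    (pool$pos[i] == pool$pos[best] &&
                       pool$snp_id[i] < pool$snp_id[best])))))
      if (better) best <- i
    }
    idx <- pool[best, ]
    index <- c(index, idx$snp_id)
    drop_i <- best
    for (i in seq_len(nrow(pool))) {
      if (i == best) next
      if (pool$chrom[i] == idx$chrom &&
          abs(pool$pos[i] - idx$pos) <= window_kb * 1000 &&
          r2Hand(panel[, idx$snp_id], panel[, pool$snp_id[i]]) > r2_thresh)
        drop_i <- c(drop_i, i)
    }
    pool <- pool[-drop_i, , drop = FALSE]
  }
  index
}

# Random summary-statistics + LD-panel fixture for clumping tests. Panel
# columns are built with blockwise correlation so some pairs exceed any
# reasonable r^2 threshold.
makeClumpFixture <- function(n_snps, seed, n_ind = 60) {
  set.seed(seed)
  chrom <- sample(c("1", "2"), n_snps, replace = TRUE)
  pos <- sample(1:2000, n_snps) * 1000L
  stats <- data.frame(
    snp_id = paste0("rs", seq_len(n_snps)),
    chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    beta = rnorm(n_snps, 0, 0.2), se = 0.03,
    p = 10^-runif(n_snps, 4, 12),
    stringsAsFactors = FALSE)
  base <- matrix(rbinom(n_ind * n_snps, 2, 0.4), n_ind, n_snps)
  # correlate consecutive SNP pairs by copying with flips
  for (j in seq(2, n_snps, by = 2)) {
    flip <- rbinom(n_ind, 1, 0.1) == 1
    base[, j] <- base[, j - 1]
    base[flip, j] <- rbinom(sum(flip), 2, 0.4)
  }
  colnames(base) <- stats$snp_id
  list(stats = stats, panel = base)
}
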