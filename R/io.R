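## File formats: PLINK .raw-dialect dosage files, summary-statistics TSVs.
## Coordinates are 1-based; dosage files whitespace-separated; output TSVs
## use "NA" as the missing sentinel.

.RAW_FIXED <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read an additive dosage matrix
#'
#' \code{dialect = "plink-raw"} expects the PLINK \code{--recode A} layout:
#' whitespace-separated, header \code{FID IID PAT MAT SEX PHENOTYPE}
#' followed by one \code{SNPID_COUNTEDALLELE} column per variant;
#' \code{dialect = "tsv"} expects a tab-separated file whose non-ID columns
#' are all dosages named by SNP id. Dosages must be 0, 1, 2 or missing;
#' anything else is a parse error reporting the offending line.
#'
#' @param path input file.
#' @param dialect "plink-raw" or "tsv".
#' @return list with \code{dosages} (individuals x SNPs matrix, IID
#'   rownames) and \code{snps} (\code{data.frame}: snp_id, counted_allele).
#' @export
readGenotypes <- function(path, dialect = c("plink-raw", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "plink-raw") "" else "\t"
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               na.strings = c("NA", "-9"), stringsAsFactors = FALSE),
    error = function(e) stop("malformed genotype file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0)
    stop("empty genotype file: ", path, call. = FALSE)
  if (dialect == "plink-raw") {
    if (!identical(colnames(df)[seq_along(.RAW_FIXED)], .RAW_FIXED))
      stop("malformed .raw header: expected it to start with '",
           paste(.RAW_FIXED, collapse = " "), "'", call. = FALSE)
    snp_cols <- colnames(df)[-seq_along(.RAW_FIXED)]
    ids <- as.character(df$IID)
  } else {
    id_col <- intersect(c("IID", "id", "sample"), colnames(df))[1]
    if (is.na(id_col)) {
      ids <- as.character(seq_len(nrow(df)))
      snp_cols <- colnames(df)
    } else {
      ids <- as.character(df[[id_col]])
      snp_cols <- setdiff(colnames(df), id_col)
    }
  }
  if (length(snp_cols) == 0)
    stop("no dosage columns found in ", path, call. = FALSE)
  dos <- as.matrix(df[, snp_cols, drop = FALSE])
  if (!is.numeric(dos))
    stop("non-numeric dosage values in ", path, call. = FALSE)
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop("dosage outside [0, 2] at line ", bad[1, 1] + 1L, " of ", path,
         call. = FALSE)
  if (dialect == "plink-raw") {
    # "rs123_A" -> id rs123, counted allele A
    us <- regexpr("_[^_]*$", snp_cols)
    snp_id <- substr(snp_cols, 1, us - 1)
    allele <- substr(snp_cols, us + 1, nchar(snp_cols))
    colnames(dos) <- snp_id
  } else {
    snp_id <- snp_cols
    allele <- rep(NA_character_, length(snp_cols))
  }
  rownames(dos) <- ids
  list(dosages = dos,
       snps = data.frame(snp_id = snp_id, counted_allele = allele,
                         stringsAsFactors = FALSE))
}

#' Write offspring dosages in the PLINK .raw dialect
#'
#' @param cohort an \code{\linkS4class{MRCohort}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGenotypesRaw <- function(cohort, path) {
  dos <- t(offspringDosage(cohort))
  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  alleles <- if ("effect_allele" %in% colnames(rd)) rd$effect_allele
             else rep("A", ncol(dos))
  n <- nrow(dos)
  df <- data.frame(FID = seq_len(n), IID = seq_len(n), PAT = 0, MAT = 0,
                   SEX = 0, PHENOTYPE = -9, check.names = FALSE)
  dos_df <- as.data.frame(dos)
  colnames(dos_df) <- paste0(colnames(dos), "_", alleles)
  write.table(cbind(df, dos_df), path, sep = " ", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

.SUMSTAT_MAP <- c(snp_id = "SNP", chrom = "CHR", pos = "POS",
                  effect_allele = "EA", other_allele = "OA",
                  beta = "BETA", se = "SE", p = "P")

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file and validates each row
#' against the record invariants: alleles are single characters in
#' {A,C,G,T} with effect != other, \code{se > 0}, \code{p} in (0, 1],
#' \code{pos >= 1}. Invalid rows are collected in a rejects report, not
#' fatal; a missing mandatory column is a configuration error.
#'
#' @param path input TSV.
#' @param column_map named character vector mapping record fields
#'   (\code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}, \code{se}, \code{p}) to file column
#'   names; defaults to \code{SNP/CHR/POS/EA/OA/BETA/SE/P}.
#' @return list with \code{records} (validated \code{data.frame}) and
#'   \code{rejects} (\code{data.frame} with a \code{reason} column).
#' @export
readSumstats <- function(path, column_map = .SUMSTAT_MAP) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(column_map), colnames(df))
  if (length(missing))
    stop("summary-statistics file lacks mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rec <- df[, unname(column_map), drop = FALSE]
  colnames(rec) <- names(column_map)
  rec$chrom <- as.character(rec$chrom)
  rec$effect_allele <- toupper(rec$effect_allele)
  rec$other_allele <- toupper(rec$other_allele)
  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(!(rec$effect_allele %in% c("A", "C", "G", "T")) |
         !(rec$other_allele %in% c("A", "C", "G", "T")),
       "allele not a single base in {A,C,G,T}")
  flag(rec$effect_allele == rec$other_allele,
       "effect and other allele identical")
  flag(is.na(rec$pos) | rec$pos < 1, "position must be >= 1")
  flag(is.na(rec$se) | rec$se <= 0, "se must be positive")
  flag(is.na(rec$p) | rec$p <= 0 | rec$p > 1, "p must be in (0, 1]")
  flag(is.na(rec$beta), "beta missing")
  ok <- is.na(reason)
  rejects <- rec[!ok, , drop = FALSE]
  rejects$reason <- reason[!ok]
  list(records = rec[ok, , drop = FALSE], rejects = rejects)
}

#' Write a tidy data.frame as TSV with "NA" sentinels
#'
#' @param x a \code{data.frame}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResultTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
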