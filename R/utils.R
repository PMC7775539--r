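#' @useDynLib crossgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor lm mahalanobis median model.matrix optimize
#'   predict quantile resid rnorm runif rbinom rchisq sd setNames var
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check that a genotype matrix is well formed
#'
#' A genotype matrix is an integer-valued matrix of allele doses (0, 1, 2;
#' `NA` for missing calls) with unique sample ids as row names and unique
#' SNP ids as column names.
#'
#' @param geno matrix to validate.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @keywords internal
check_geno <- function(geno) {
  if (!is.matrix(geno)) stopf("genotypes must be a matrix")
  if (is.null(rownames(geno)) || anyDuplicated(rownames(geno)))
    stopf("genotype matrix needs unique sample ids as rownames")
  if (is.null(colnames(geno)) || anyDuplicated(colnames(geno)))
    stopf("genotype matrix needs unique SNP ids as colnames")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stopf("allele doses must be 0, 1, 2 or NA")
  invisible(geno)
}

# Column means with NAs ignored; columns that are all-NA get mean 0.
col_means_safe <- function(x) {
  m <- colMeans(x, na.rm = TRUE)
  m[!is.finite(m)] <- 0
  m
}

#' Mean-impute missing allele doses
#'
#' Replaces each missing dose by its SNP (column) mean computed on the
#' non-missing calls, the standard light-touch imputation used ahead of
#' correlation pruning and GRM construction.
#'
#' @param geno genotype matrix (doses 0/1/2, `NA` missing).
#' @return a numeric matrix with no missing values.
#' @export
impute_mean <- function(geno) {
  check_geno(geno)
  g <- geno
  storage.mode(g) <- "double"
  if (anyNA(g)) {
    m <- col_means_safe(g)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- m[idx[, 2]]
  }
  g
}

# Deterministic per-purpose seed derived from a base seed; keeps values
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}
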