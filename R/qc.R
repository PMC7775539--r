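new_qc_report <- function(rule, axis, dropped, retained) {
  structure(list(rule = rule, axis = axis,
                 n_dropped = length(dropped), n_retained = length(retained),
                 dropped = dropped, retained = retained),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC rule '%s' (%s axis): %d dropped, %d retained\n",
              x$rule, x$axis, x$n_dropped, x$n_retained))
  invisible(x)
}

#' SNP call-rate and minor-allele-frequency filter
#'
#' Drops a SNP when its call rate (fraction of non-missing doses) is below
#' `call_rate_min` or its minor allele frequency, computed on non-missing
#' calls, is below `maf_min` (strict: MAF exactly at the threshold is kept).
#'
#' @param geno dose matrix (0/1/2, NA missing).
#' @param call_rate_min minimum call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list with `geno` (filtered matrix) and `report` (a `qc_report`).
#' @export
snp_qc <- function(geno, call_rate_min = 0.90, maf_min = 0.05) {
  check_geno(geno)
  obs <- colMeans(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  p[!is.finite(p)] <- 0
  maf <- pmin(p, 1 - p)
  keep <- obs >= call_rate_min & maf >= maf_min
  if (!any(keep)) stopf("SNP QC dropped every SNP")
  new_geno <- geno[, keep, drop = FALSE]
  list(geno = new_geno,
       report = new_qc_report("snp_callrate_maf", "snp",
                              colnames(geno)[!keep], colnames(new_geno)))
}

#' Sample call-rate filter
#'
#' Drops samples whose fraction of non-missing doses (over the SNPs that
#' survived SNP-level QC) is below `call_rate_min`.
#'
#' @inheritParams snp_qc
#' @return list with `geno` and `report`.
#' @export
sample_qc <- function(geno, call_rate_min = 0.90) {
  check_geno(geno)
  obs <- rowMeans(!is.na(geno))
  keep <- obs >= call_rate_min
  if (!any(keep)) stopf("sample QC dropped every sample")
  new_geno <- geno[keep, , drop = FALSE]
  list(geno = new_geno,
       report = new_qc_report("sample_callrate", "sample",
                              rownames(geno)[!keep], rownames(new_geno)))
}

#' Detect Mendelian inconsistencies in parent-offspring pairs
#'
#' A locus is inconsistent when parent and offspring are opposite
#' homozygotes (doses 0 vs 2); a heterozygous parent can never be
#' inconsistent. A pair is flagged when the inconsistent fraction over the
#' jointly non-missing loci exceeds `tol`. Pairs with zero jointly typed
#' loci are skipped with a message.
#'
#' @param geno dose matrix.
#' @param pedigree pedigree data frame (id, sire, dam).
#' @param tol maximum tolerated inconsistency rate (default 0.01).
#' @return data frame with one row per checked pair: `parent`, `offspring`,
#'   `n_checked`, `n_inconsistent`, `rate`, `flagged`.
#' @export
mendel_check <- function(geno, pedigree, tol = 0.01) {
  check_geno(geno)
  typed <- rownames(geno)
  rows <- list()
  for (i in seq_len(nrow(pedigree))) {
    off <- pedigree$id[i]
    if (!(off %in% typed)) next
    for (par in c(pedigree$sire[i], pedigree$dam[i])) {
      if (is.na(par) || !(par %in% typed)) next
      po <- geno[par, ]; oo <- geno[off, ]
      both <- !is.na(po) & !is.na(oo)
      n <- sum(both)
      if (n == 0) {
        message(sprintf("mendel_check: pair %s-%s has no jointly typed loci; skipped",
                        par, off))
        next
      }
      bad <- sum((po[both] == 0L & oo[both] == 2L) |
                   (po[both] == 2L & oo[both] == 0L))
      rows[[length(rows) + 1L]] <-
        data.frame(parent = par, offspring = off, n_checked = n,
                   n_inconsistent = bad, rate = bad / n,
                   flagged = (bad / n) > tol, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(parent = character(0), offspring = character(0),
                      n_checked = integer(0), n_inconsistent = integer(0),
                      rate = numeric(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Near-zero-variance SNP filter
#'
#' Tabulates the genotype values (0/1/2) of each SNP and drops it when it
#' has zero variance or when the ratio of the most common to the second most
#' common value count exceeds `freq_ratio_cutoff` (default 95/5 = 19).
#'
#' @param geno dose matrix.
#' @param freq_ratio_cutoff maximum allowed frequency ratio (default 19).
#' @return list with `geno` and `report`.
#' @export
near_zero_variance_filter <- function(geno, freq_ratio_cutoff = 95 / 5) {
  check_geno(geno)
  drop <- vapply(seq_len(ncol(geno)), function(j) {
    tab <- sort(table(geno[, j]), decreasing = TRUE)
    if (length(tab) < 2) return(TRUE)            # constant column
    (tab[1] / tab[2]) > freq_ratio_cutoff
  }, TRUE)
  new_geno <- geno[, !drop, drop = FALSE]
  list(geno = new_geno,
       report = new_qc_report("near_zero_variance", "snp",
                              colnames(geno)[drop], colnames(new_geno)))
}

#' Greedy correlation pruning of SNP features
#'
#' Computes the absolute Pearson correlation matrix of the dose columns
#' (missing doses mean-imputed first) and, while any pair exceeds `cutoff`,
#' removes from the worst offending pair the member with the larger mean
#' absolute correlation to all remaining features (ties: the lower column
#' index is removed). After pruning no retained pair has |r| above the
#' cutoff.
#'
#' @param geno dose matrix.
#' @param cutoff maximum allowed absolute pairwise correlation (default 0.8).
#' @return list with `geno` and `report`.
#' @export
correlation_prune <- function(geno, cutoff = 0.8) {
  check_geno(geno)
  g <- impute_mean(geno)
  m <- ncol(g)
  if (m < 2)
    return(list(geno = geno,
                report = new_qc_report("correlation_prune", "snp",
                                       character(0), colnames(geno))))
  sds <- apply(g, 2, sd)
  if (any(sds == 0))
    stopf("correlation_prune expects no zero-variance columns; run near_zero_variance_filter first")
  cm <- abs(cor(g))
  diag(cm) <- 0
  alive <- rep(TRUE, m)
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    mx <- max(sub)
    if (mx <= cutoff) break
    idx_alive <- which(alive)
    w <- which(sub == mx, arr.ind = TRUE)[1, ]   # first worst pair (row order)
    pair <- idx_alive[sort(w)]
    mean_abs <- rowMeans(cm[pair, alive, drop = FALSE])
    # remove the member with larger mean |r|; ties -> lower column index
    victim <- if (mean_abs[1] >= mean_abs[2]) pair[1] else pair[2]
    alive[victim] <- FALSE
  }
  new_geno <- geno[, alive, drop = FALSE]
  list(geno = new_geno,
       report = new_qc_report("correlation_prune", "snp",
                              colnames(geno)[!alive], colnames(new_geno)))
}

#' Restrict a crossbred panel to the purebred retained SNP set
#'
#' Keeps in the CB genotype matrix exactly the SNPs retained for the PB
#' panel, in PB panel order, so that features used for prediction segregate
#' in the purebred line.
#'
#' @param geno_cb CB dose matrix.
#' @param retained_pb_snp_ids character vector of retained PB SNP ids.
#' @return the restricted CB matrix, columns in PB panel order.
#' @export
harmonize_panels <- function(geno_cb, retained_pb_snp_ids) {
  check_geno(geno_cb)
  if (!length(retained_pb_snp_ids)) stopf("retained PB panel is empty")
  missing <- setdiff(retained_pb_snp_ids, colnames(geno_cb))
  if (length(missing))
    stopf("PB panel SNPs absent from CB genotypes: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  geno_cb[, retained_pb_snp_ids, drop = FALSE]
}

#' Full genotype quality-control cascade
#'
#' Applies the QC stages in their fixed order: SNP call-rate/MAF filter,
#' sample call-rate filter, Mendelian-consistency check (flagged pairs'
#' offspring removed), then -- per data subset of samples -- the
#' near-zero-variance filter and greedy correlation pruning.
#'
#' @param geno dose matrix covering all animals.
#' @param pedigree pedigree data frame.
#' @param subsets named list of sample-id vectors (one per data subset); per
#'   subset a pruned SNP panel is produced. NULL skips the per-subset stage.
#' @param call_rate_min,maf_min,mendel_tol,freq_ratio_cutoff,corr_cutoff
#'   stage thresholds.
#' @return object of class `qc_result`: list with `geno` (after the global
#'   stages), `reports` (list of `qc_report`s), `mendel` (pair table), and
#'   `panels` (named list of retained SNP-id vectors per subset).
#' @export
qc_pipeline <- function(geno, pedigree, subsets = NULL,
                        call_rate_min = 0.90, maf_min = 0.05,
                        mendel_tol = 0.01, freq_ratio_cutoff = 95 / 5,
                        corr_cutoff = 0.8) {
  s1 <- snp_qc(geno, call_rate_min, maf_min)
  s2 <- sample_qc(s1$geno, call_rate_min)
  mend <- mendel_check(s2$geno, pedigree, mendel_tol)
  bad_off <- unique(mend$offspring[mend$flagged])
  g <- s2$geno[setdiff(rownames(s2$geno), bad_off), , drop = FALSE]
  mend_report <- new_qc_report("mendelian", "sample", bad_off, rownames(g))
  reports <- list(snp = s1$report, sample = s2$report, mendel = mend_report)
  panels <- NULL
  if (!is.null(subsets)) {
    panels <- lapply(names(subsets), function(nm) {
      idsub <- intersect(subsets[[nm]], rownames(g))
      if (!length(idsub)) stopf("subset '%s' has no genotyped samples", nm)
      gs <- g[idsub, , drop = FALSE]
      nzv <- near_zero_variance_filter(gs, freq_ratio_cutoff)
      pr <- correlation_prune(nzv$geno, corr_cutoff)
      reports[[paste0("nzv_", nm)]] <<- nzv$report
      reports[[paste0("prune_", nm)]] <<- pr$report
      colnames(pr$geno)
    })
    names(panels) <- names(subsets)
  }
  structure(list(geno = g, reports = reports, mendel = mend,
                 panels = panels),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype QC cascade\n")
  for (r in x$reports)
    cat(sprintf("  %-22s %-6s dropped %5d retained %5d\n",
                r$rule, r$axis, r$n_dropped, r$n_retained))
  if (!is.null(x$panels))
    for (nm in names(x$panels))
      cat(sprintf("  panel '%s': %d SNPs\n", nm, length(x$panels[[nm]])))
  invisible(x)
}
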