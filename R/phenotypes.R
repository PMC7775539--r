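#' Metabolic weight
#'
#' Mid-test body weight raised to the power 0.75, the standard maintenance
#' requirement proxy: MW = ((w_start + w_end) / 2)^0.75. Units are kg^0.75.
#'
#' @param w_start,w_end weights (kg) at the start and end of the test period.
#' @return numeric vector of metabolic weights.
#' @export
metabolic_weight <- function(w_start, w_end) {
  if (any(w_start < 0, na.rm = TRUE) || any(w_end < 0, na.rm = TRUE))
    stopf("weights must be non-negative")
  ((w_start + w_end) / 2)^0.75
}

#' Retain records inside the performance-test window
#'
#' Keeps records of animals that started the test (or grower-finisher
#' period) between 50 and 105 days of age and stayed on test between 60 and
#' 120 days. Bounds are inclusive.
#'
#' @param records phenotype data frame with `age_start` and `duration`.
#' @param age_bounds,duration_bounds inclusive bounds (days).
#' @return the retained records.
#' @export
filter_test_window <- function(records, age_bounds = c(50, 105),
                               duration_bounds = c(60, 120)) {
  stopifnot(all(c("age_start", "duration") %in% names(records)))
  keep <- records$age_start >= age_bounds[1] & records$age_start <= age_bounds[2] &
    records$duration >= duration_bounds[1] & records$duration <= duration_bounds[2]
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Flag multivariate outliers by squared Mahalanobis distance
#'
#' Within each group (farm x batch for purebreds, farm x batch x sex for
#' crossbreds), computes the squared Mahalanobis distance of each record's
#' (ADG, DFI, backfat, MW) vector to the group mean using the group sample
#' covariance, and flags records with squared distance above `threshold`.
#' Groups with fewer than `min_group` records are skipped with a warning
#' (nothing flagged there); a singular covariance falls back to the
#' Moore-Penrose pseudo-inverse.
#'
#' @param records phenotype data frame; must contain `vars` and `group_cols`.
#' @param group_cols character vector of grouping columns.
#' @param threshold squared-distance cutoff (default 12).
#' @param vars trait columns entering the distance.
#' @param min_group minimum group size for a stable covariance.
#' @return logical vector, TRUE = flagged outlier.
#' @export
flag_outliers_mahalanobis <- function(records,
                                      group_cols = c("farm", "batch"),
                                      threshold = 12,
                                      vars = c("adg", "dfi", "backfat", "mw"),
                                      min_group = 6) {
  stopifnot(all(vars %in% names(records)), all(group_cols %in% names(records)))
  flag <- rep(FALSE, nrow(records))
  grp <- interaction(records[group_cols], drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < min_group) {
      warnf("outlier group '%s' has %d < %d records; skipped", g,
            length(idx), min_group)
      next
    }
    x <- as.matrix(records[idx, vars])
    ctr <- colMeans(x)
    cv <- stats::cov(x)
    d2 <- tryCatch(mahalanobis(x, ctr, cv),
                   error = function(e) {
                     message(sprintf(
                       "singular covariance in group '%s'; using pseudo-inverse", g))
                     mahalanobis(x, ctr, MASS::ginv(cv), inverted = TRUE)
                   })
    flag[idx] <- d2 > threshold
  }
  flag
}

#' Derive residual feed intake
#'
#' RFI is the residual of an ordinary least squares regression of daily feed
#' intake on average daily gain, backfat thickness and metabolic weight
#' (with intercept), fitted within the data subset at hand.
#'
#' @param records phenotype data frame with `dfi`, `adg`, `backfat`, `mw`
#'   and `id` columns.
#' @return data frame with columns `id` and `rfi` (g/day).
#' @export
derive_rfi <- function(records) {
  stopifnot(all(c("id", "dfi", "adg", "backfat", "mw") %in% names(records)))
  if (nrow(records) <= 4)
    stopf("RFI regression needs more than 4 records (got %d)", nrow(records))
  X <- cbind(1, records$adg, records$backfat, records$mw)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cols <- c("(intercept)", "adg", "backfat", "mw")
    bad <- cols[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("RFI design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  fit <- lm(dfi ~ adg + backfat + mw, data = records)
  data.frame(id = records$id, rfi = as.numeric(resid(fit)),
             stringsAsFactors = FALSE)
}

#' Pre-adjust a trait for systematic environmental effects
#'
#' Drops farm-by-batch levels with fewer than `min_level` records, then fits
#' a linear model of the trait on age at the start of the test (covariate),
#' test duration (covariate), farm x batch, and sex (crossbred subsets
#' only). The adjusted value is the observed value minus the estimated
#' non-intercept systematic part, i.e. residual plus the fitted intercept,
#' so trait means stay on their original scale.
#'
#' @param records data frame with the trait column plus `age_start`,
#'   `duration`, `farm`, `batch` (and `sex` if `include_sex`).
#' @param trait name of the trait column (e.g. `"rfi"` or `"adg"`).
#' @param include_sex include sex in the model (crossbred subsets).
#' @param min_level minimum records per farm-by-batch level (default 10).
#' @return data frame with columns `id` and `value` (the adjusted trait);
#'   attribute `"dropped_levels"` lists removed farm-by-batch levels.
#' @export
preadjust_trait <- function(records, trait, include_sex = FALSE,
                            min_level = 10) {
  need <- c("id", trait, "age_start", "duration", "farm", "batch",
            if (include_sex) "sex")
  stopifnot(all(need %in% names(records)))
  fb <- interaction(records$farm, records$batch, drop = TRUE)
  counts <- table(fb)
  keep_lv <- names(counts)[counts >= min_level]
  dropped <- setdiff(names(counts), keep_lv)
  if (!length(keep_lv))
    stopf("all farm x batch levels have fewer than %d records", min_level)
  keep <- fb %in% keep_lv
  dat <- records[keep, , drop = FALSE]
  dat$fb <- droplevels(factor(interaction(dat$farm, dat$batch, drop = TRUE)))
  form <- sprintf("%s ~ age_start + duration%s%s", trait,
                  if (nlevels(dat$fb) > 1) " + fb" else "",
                  if (include_sex && length(unique(dat$sex)) > 1) " + sex" else "")
  fit <- lm(stats::as.formula(form), data = dat)
  adjusted <- as.numeric(resid(fit)) + coef(fit)[["(Intercept)"]]
  out <- data.frame(id = dat$id, value = adjusted, stringsAsFactors = FALSE)
  attr(out, "dropped_levels") <- dropped
  out
}

#' Average adjusted crossbred records per purebred sire
#'
#' @param adjusted data frame (`id`, `value`) of adjusted CB records.
#' @param pedigree pedigree data frame linking CB ids to their sires.
#' @return data frame with `sire_id`, `mean`, `n` (one row per sire with at
#'   least one retained offspring record).
#' @export
sire_average <- function(adjusted, pedigree) {
  stopifnot(all(c("id", "value") %in% names(adjusted)))
  sire <- pedigree$sire[match(adjusted$id, pedigree$id)]
  known <- !is.na(sire)
  if (any(!known))
    message(sprintf("sire_average: %d record(s) with unknown sire excluded",
                    sum(!known)))
  if (!any(known))
    return(data.frame(sire_id = character(0), mean = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  sp <- split(adjusted$value[known], sire[known])
  data.frame(sire_id = names(sp),
             mean = vapply(sp, mean, 0),
             n = vapply(sp, length, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Prepare adjusted traits for one data subset
#'
#' Runs the full phenotype pipeline in its fixed order: test-window filter,
#' multivariate outlier removal, RFI derivation, environmental
#' pre-adjustment of RFI and ADG, and (for the sire-average subset) the
#' per-sire averaging of adjusted CB records. Outlier groups are
#' farm x batch for the purebred subset and farm x batch x sex for
#' crossbred subsets.
#'
#' @param records raw phenotype records (one subset: dPB, dCB_sire or dCB).
#' @param pedigree pedigree data frame (needed for sire averaging).
#' @param subset one of `"pb"`, `"cb_sire"`, `"cb"`.
#' @param mahal_threshold squared Mahalanobis cutoff (default 12).
#' @return object of class `prepped_phenotypes`: list with `adjusted`
#'   (data frame id, rfi, adg), `sire_means` (for `"cb_sire"`: data frame
#'   sire_id, rfi, adg, n), and `report` (records retained per stage).
#' @export
prep_phenotypes <- function(records, pedigree = NULL,
                            subset = c("pb", "cb_sire", "cb"),
                            mahal_threshold = 12) {
  subset <- match.arg(subset)
  is_cb <- subset != "pb"
  n0 <- nrow(records)
  rec <- filter_test_window(records)
  n_window <- nrow(rec)
  if (!("mw" %in% names(rec)))
    rec$mw <- metabolic_weight(rec$w_start, rec$w_end)
  grp <- if (is_cb) c("farm", "batch", "sex") else c("farm", "batch")
  out_flag <- flag_outliers_mahalanobis(rec, group_cols = grp,
                                        threshold = mahal_threshold)
  rec <- rec[!out_flag, , drop = FALSE]
  n_outlier <- nrow(rec)
  rfi <- derive_rfi(rec)
  rec$rfi <- rfi$rfi[match(rec$id, rfi$id)]
  adj_rfi <- preadjust_trait(rec, "rfi", include_sex = is_cb)
  adj_adg <- preadjust_trait(rec, "adg", include_sex = is_cb)
  ids <- intersect(adj_rfi$id, adj_adg$id)
  adjusted <- data.frame(id = ids,
                         rfi = adj_rfi$value[match(ids, adj_rfi$id)],
                         adg = adj_adg$value[match(ids, adj_adg$id)],
                         stringsAsFactors = FALSE)
  sire_means <- NULL
  if (subset == "cb_sire") {
    if (is.null(pedigree)) stopf("pedigree required for sire averaging")
    sa_rfi <- sire_average(adjusted[, c("id", "rfi")] |>
                             setNames(c("id", "value")), pedigree)
    sa_adg <- sire_average(adjusted[, c("id", "adg")] |>
                             setNames(c("id", "value")), pedigree)
    sire_means <- data.frame(sire_id = sa_rfi$sire_id,
                             rfi = sa_rfi$mean,
                             adg = sa_adg$mean[match(sa_rfi$sire_id, sa_adg$sire_id)],
                             n = sa_rfi$n, stringsAsFactors = FALSE)
  }
  structure(list(adjusted = adjusted, sire_means = sire_means,
                 report = c(input = n0, window = n_window,
                            outlier = n_outlier, adjusted = nrow(adjusted)),
                 subset = subset),
            class = "prepped_phenotypes")
}

#' @export
print.prepped_phenotypes <- function(x, ...) {
  cat(sprintf("Prepared phenotypes (%s subset)\n", x$subset))
  cat(sprintf("  records: %d input -> %d in window -> %d after outliers -> %d adjusted\n",
              x$report["input"], x$report["window"], x$report["outlier"],
              x$report["adjusted"]))
  if (!is.null(x$sire_means))
    cat(sprintf("  sire averages: %d sires, median offspring n = %g\n",
                nrow(x$sire_means), median(x$sire_means$n)))
  invisible(x)
}
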