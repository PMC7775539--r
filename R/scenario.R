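#' Spearman correlation between observed and predicted values
#'
#' Rank correlation with average ranks for ties, the accuracy measure used
#' throughout the evaluation design. Constant predictions (or observations)
#' give a correlation of 0 with attribute `"degenerate"` set, so degenerate
#' learners yield an interpretable null rather than an error mid-pipeline.
#'
#' @param obs,pred numeric vectors of equal length (>= 3).
#' @return the Spearman correlation.
#' @export
spearman_sc <- function(obs, pred) {
  if (length(obs) < 3 || length(pred) != length(obs))
    stopf("spearman_sc needs >= 3 observed/predicted pairs")
  if (sd(obs) == 0 || sd(pred) == 0)
    return(structure(0, degenerate = TRUE))
  cor(obs, pred, method = "spearman")
}

#' Median and interquartile range of fold correlations
#'
#' @param values numeric vector of per-fold Spearman correlations.
#' @return named vector with `median` and `iqr` (Q3 - Q1, linear
#'   interpolation quantiles).
#' @export
summarize_sc <- function(values) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Bootstrap distribution of the Spearman correlation
#'
#' Resamples observed/predicted pairs with replacement `B` times (resample
#' size = number of pairs), computes the Spearman correlation of each
#' resample, and summarizes the bootstrap distribution by its median and
#' interquartile range. Used for the single-split generational scenarios
#' where no cross-validation spread is available. Degenerate resamples
#' (constant ranks) contribute 0 and are counted.
#'
#' @param obs,pred numeric vectors (>= 3 pairs).
#' @param B number of bootstrap resamples (default 500).
#' @param seed RNG seed.
#' @return list with `median`, `iqr`, `values` (the B correlations) and
#'   `n_degenerate`.
#' @export
bootstrap_sc <- function(obs, pred, B = 500, seed = 1) {
  if (length(obs) < 3 || length(pred) != length(obs))
    stopf("bootstrap_sc needs >= 3 pairs")
  set.seed(seed)
  n <- length(obs)
  degen <- 0L
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    sc <- spearman_sc(obs[idx], pred[idx])
    if (isTRUE(attr(sc, "degenerate"))) degen <<- degen + 1L
    as.numeric(sc)
  }, 0)
  s <- summarize_sc(vals)
  list(median = unname(s["median"]), iqr = unname(s["iqr"]), values = vals,
       n_degenerate = degen)
}

#' Rank SNPs by Spearman correlation with the trait
#'
#' Computes the Spearman rank correlation (average ranks for ties) between
#' each SNP column and the training response, and orders SNPs by decreasing
#' absolute correlation (ties broken by column index, so the ranking is
#' deterministic). Constant columns get correlation 0 and rank last.
#'
#' @param X training dose/feature matrix.
#' @param y training response.
#' @return character vector of SNP ids in rank order, with the correlations
#'   as attribute `"rho"`.
#' @export
rank_snps_spearman <- function(X, y) {
  if (nrow(X) < 3) stopf("need at least 3 training rows to rank SNPs")
  ry <- rank(y)
  rx <- apply(X, 2, rank)
  sds <- apply(rx, 2, sd)
  const <- sds == 0
  if (any(const))
    message(sprintf("rank_snps_spearman: %d constant SNP(s) ranked last",
                    sum(const)))
  rho <- rep(0, ncol(X))
  if (any(!const))
    rho[!const] <- suppressWarnings(
      as.numeric(cor(rx[, !const, drop = FALSE], ry)))
  ord <- order(-abs(rho), seq_along(rho))
  structure(colnames(X)[ord], rho = rho[ord])
}

#' Select the top-k ranked SNPs
#'
#' @param ranked_ids ranked SNP ids from [rank_snps_spearman()].
#' @param k subset size; the default evaluation grid is 50, 250, 500, 750,
#'   1000, 1500, 2000.
#' @return the first k ids.
#' @export
select_top_k <- function(ranked_ids, k) {
  if (k > length(ranked_ids))
    stopf("k = %d exceeds the panel size %d", k, length(ranked_ids))
  ranked_ids[seq_len(k)]
}

# Random near-equal-size fold assignment; returns a list of index vectors.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  unname(split(idx, rep_len(seq_len(k), n)))
}

#' Build a cross-validation plan
#'
#' Splits ids into k near-equal folds, optionally repeated; when `families`
#' is given (e.g. the sire of each crossbred animal), whole families are
#' assigned to folds so that no training animal shares a family with a test
#' animal -- the progeny-exclusion constraint of the CB-training scenario.
#'
#' @param ids unique unit ids.
#' @param k folds per repeat.
#' @param repeats number of repeats (default 1).
#' @param seed RNG seed; the plan is deterministic given it.
#' @param families optional vector (parallel to ids) of family labels.
#' @return object of class `cv_plan`: list `repeats` of lists of k
#'   `list(train, test)` id sets.
#' @export
build_cv_plan <- function(ids, k, repeats = 1, seed = 1, families = NULL) {
  if (anyDuplicated(ids)) stopf("ids must be unique")
  n <- length(ids)
  if (!is.null(families) && length(families) != n)
    stopf("families must parallel ids")
  plans <- lapply(seq_len(repeats), function(r) {
    rs <- derive_seed(seed, 1000L + r)
    if (is.null(families)) {
      folds <- make_folds(n, k, rs)
    } else {
      fams <- unique(families)
      if (length(fams) < k)
        stopf("fewer families (%d) than folds (%d)", length(fams), k)
      set.seed(rs)
      fams <- sample(fams)
      sizes <- numeric(k)
      fold_of_fam <- setNames(integer(length(fams)), fams)
      for (f in fams) {                     # greedy balance by member count
        tgt <- which.min(sizes)
        fold_of_fam[f] <- tgt
        sizes[tgt] <- sizes[tgt] + sum(families == f)
      }
      folds <- lapply(seq_len(k), function(j)
        which(fold_of_fam[as.character(families)] == j))
    }
    lapply(folds, function(te)
      list(train = ids[-te], test = ids[te]))
  })
  structure(list(folds = plans, ids = ids, k = k, repeats = repeats,
                 seed = seed, by_family = !is.null(families)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("CV plan: %d ids, %d-fold x %d repeat(s)%s, seed %d\n",
              length(x$ids), x$k, x$repeats,
              if (x$by_family) " (family-blocked)" else "", x$seed))
  invisible(x)
}

#' Assign generation numbers from a pedigree
#'
#' Founders (both parents unknown or outside the pedigree) get generation
#' 0; any other animal gets 1 plus the maximum generation of its known
#' parents. A pedigree cycle is an error naming the animals involved.
#'
#' @param pedigree data frame with id, sire, dam.
#' @return named integer vector id -> generation.
#' @export
assign_generations <- function(pedigree) {
  ids <- pedigree$id
  if (anyDuplicated(ids)) stopf("duplicate ids in pedigree")
  sire <- ifelse(pedigree$sire %in% ids, pedigree$sire, NA)
  dam <- ifelse(pedigree$dam %in% ids, pedigree$dam, NA)
  gen <- setNames(rep(NA_integer_, length(ids)), ids)
  gen[is.na(sire) & is.na(dam)] <- 0L
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progress <- FALSE
    for (i in todo) {
      pg <- c(if (!is.na(sire[i])) gen[sire[i]],
              if (!is.na(dam[i])) gen[dam[i]])
      if (!anyNA(pg)) {
        gen[i] <- 1L + max(pg)
        progress <- TRUE
      }
    }
    if (!progress)
      stopf("pedigree cycle involving: %s",
            paste(utils::head(ids[is.na(gen)], 10), collapse = ", "))
  }
  gen
}

#' Split units into OLD training and YOUNG testing sets by generation
#'
#' Animals from the last `n_young` generations present among `ids` form the
#' testing set; the rest form the training set. This is a single split
#' (no cross-validation), mirroring prediction of the current selection
#' candidates from all earlier generations.
#'
#' @param pedigree pedigree data frame.
#' @param ids unit ids to split.
#' @param n_young number of youngest generations tested (default 2).
#' @return list with `train` and `test` id vectors.
#' @export
split_generational <- function(pedigree, ids, n_young = 2) {
  if (n_young < 1) stopf("n_young must be >= 1 (empty test set is invalid)")
  gen <- assign_generations(pedigree)[ids]
  if (anyNA(gen)) stopf("ids missing from pedigree")
  gens <- sort(unique(gen))
  if (length(gens) < n_young + 1)
    stopf("need more than n_young = %d distinct generations (found %d)",
          n_young, length(gens))
  young <- gens[(length(gens) - n_young + 1):length(gens)]
  list(train = ids[!(gen %in% young)], test = ids[gen %in% young])
}

#' Partition test sires into IN and OUT of training
#'
#' IN training sires have their own individual purebred record in the
#' training set; OUT sires do not. Performance is reported separately per
#' group.
#'
#' @param train_ids_pb ids in the purebred training set.
#' @param test_sire_ids sires evaluated in the sire-average testing set.
#' @return list with `in_sires` and `out_sires`.
#' @export
partition_in_out <- function(train_ids_pb, test_sire_ids) {
  list(in_sires = intersect(test_sire_ids, train_ids_pb),
       out_sires = setdiff(test_sire_ids, train_ids_pb))
}

#' Specify an evaluation scenario
#'
#' Valid combinations mirror the crossbred-evaluation design: `trn1-tst1` (purebred
#' records predicting purebred records, 10-fold), `trn1-tst2` (purebred
#' training, sire-average testing with IN/OUT partitioning, same 10-fold),
#' `trn2-tst2` (sire-average training and testing, 5-fold x 5) and
#' `trn3-tst2` (individual crossbred training, sire-average testing with
#' family-blocked 5-fold x 5). `split = "generational"` replaces the k-fold
#' design with a single OLD-training / YOUNG-testing realization.
#'
#' @param training `"trn1"`, `"trn2"` or `"trn3"`.
#' @param testing `"tst1"` or `"tst2"`.
#' @param learner `"svr"` or `"gblup"`.
#' @param subset_sizes SNP subset sizes for the SVR feature-selection path.
#' @param split `"kfold"` or `"generational"`.
#' @param k,repeats outer-CV geometry; defaults follow the design (10 x 1
#'   for trn1-tst1, 5 x 5 otherwise).
#' @param n_young youngest generations in the generational test set.
#' @param C_grid,gamma_grid,epsilon,inner_k SVR tuning settings.
#' @param rank_on `"train"` (correct, default) or `"all"` -- ranking SNPs on
#'   all data before cross-validation, provided only to demonstrate the
#'   selection-bias leak.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(training, testing, learner = c("svr", "gblup"),
                          subset_sizes = c(50, 250, 500, 750, 1000, 1500, 2000),
                          split = c("kfold", "generational"),
                          k = NULL, repeats = NULL, n_young = 2,
                          C_grid = c(0.001, 0.1, 1, 5, 10),
                          gamma_grid = c(0.005, 0.05, 0.5, 5),
                          epsilon = 0.1, inner_k = 6,
                          rank_on = c("train", "all")) {
  learner <- match.arg(learner)
  split <- match.arg(split)
  rank_on <- match.arg(rank_on)
  combo <- paste(training, testing, sep = "-")
  valid <- c("trn1-tst1", "trn1-tst2", "trn2-tst2", "trn3-tst2")
  if (!combo %in% valid)
    stopf("invalid scenario %s; valid: %s", combo, paste(valid, collapse = ", "))
  k <- k %||% if (combo == "trn1-tst1" || combo == "trn1-tst2") 10 else 5
  repeats <- repeats %||% if (combo %in% c("trn2-tst2", "trn3-tst2")) 5 else 1
  structure(list(training = training, testing = testing, combo = combo,
                 learner = learner, subset_sizes = subset_sizes,
                 split = split, k = k, repeats = repeats, n_young = n_young,
                 C_grid = C_grid, gamma_grid = gamma_grid, epsilon = epsilon,
                 inner_k = inner_k, rank_on = rank_on),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s, learner %s, %s split", x$combo, x$learner, x$split))
  if (x$split == "kfold")
    cat(sprintf(" (%d-fold x %d)", x$k, x$repeats))
  cat("\n")
  if (x$learner == "svr")
    cat(sprintf("  SNP subsets: %s; C in {%s}; gamma in {%s}; epsilon %g\n",
                paste(x$subset_sizes, collapse = ", "),
                paste(x$C_grid, collapse = ", "),
                paste(x$gamma_grid, collapse = ", "), x$epsilon))
  invisible(x)
}

#' Bundle the data needed by the evaluation scenarios
#'
#' @param geno post-QC dose matrix over all animals.
#' @param pedigree pedigree data frame.
#' @param pb_pheno data frame (id, value): adjusted purebred trait.
#' @param cb_pheno data frame (id, value): adjusted individual CB trait.
#' @param sire_pheno data frame (sire_id, value, n): sire averages.
#' @param panel_pb,panel_sire retained SNP ids for the PB and sire panels.
#' @return object of class `scenario_data`.
#' @export
scenario_data <- function(geno, pedigree, pb_pheno, cb_pheno, sire_pheno,
                          panel_pb, panel_sire) {
  stopifnot(all(c("id", "value") %in% names(pb_pheno)),
            all(c("id", "value") %in% names(cb_pheno)),
            all(c("sire_id", "value") %in% names(sire_pheno)))
  keep_pb <- pb_pheno$id %in% rownames(geno)
  keep_cb <- cb_pheno$id %in% rownames(geno)
  keep_s <- sire_pheno$sire_id %in% rownames(geno)
  structure(list(geno = geno, pedigree = pedigree,
                 pb_pheno = pb_pheno[keep_pb, ],
                 cb_pheno = cb_pheno[keep_cb, ],
                 sire_pheno = sire_pheno[keep_s, ],
                 panel_pb = intersect(panel_pb, colnames(geno)),
                 panel_sire = intersect(panel_sire, colnames(geno))),
            class = "scenario_data")
}

# SVR path for one outer fold: rank on the ranking set, then per subset size
# tune on the training set (inner CV) and predict the standardized test set.
svr_fold_predictions <- function(Xtr, ytr, Xte, rank_ids, spec, seed) {
  res <- list()
  for (kk in spec$subset_sizes) {
    sel <- select_top_k(rank_ids, kk)
    tun <- tune_svr(Xtr[, sel, drop = FALSE], ytr,
                    C_grid = spec$C_grid, gamma_grid = spec$gamma_grid,
                    epsilon = spec$epsilon, inner_k = spec$inner_k,
                    seed = derive_seed(seed, kk))
    fit <- svr(Xtr[, sel, drop = FALSE], ytr, C = tun$C, gamma = tun$gamma,
               epsilon = spec$epsilon, scale = FALSE, tol = 1e-4)
    res[[as.character(kk)]] <- predict(fit, Xte[, sel, drop = FALSE])
  }
  res
}

record_rows <- function(scenario, learner, subset_size, rep, fold, group,
                        ids, observed, predicted) {
  data.frame(scenario = scenario, learner = learner,
             subset_size = subset_size, rep = rep, fold = fold,
             group = group, id = ids, observed = observed,
             predicted = as.numeric(predicted), stringsAsFactors = FALSE)
}

#' Run an evaluation scenario
#'
#' Executes the full nested design for one scenario, learner and trait:
#' outer folds (or a single generational split), within-fold feature
#' standardization (training statistics for individual-record testing sets,
#' own statistics for sire-average testing sets), within-fold Spearman SNP
#' ranking, per-subset-size inner-6-fold hyper-parameter tuning, fitting
#' and test-set prediction. The GBLUP branch skips ranking and subsets and
#' uses a per-scenario VanRaden GRM over training and testing animals with
#' all post-QC SNPs; its variance components are estimated once per
#' scenario. Fold splits depend only on (ids, k, repeats, seed) so they are
#' identical across learners and subset sizes.
#'
#' @param spec a [scenario_spec()].
#' @param data a [scenario_data()] bundle.
#' @param seed integer seed controlling folds and tuning.
#' @return object of class `scenario_result`: a data frame of per-test-unit
#'   predictions (scenario, learner, subset_size, rep, fold, group, id,
#'   observed, predicted) with the CV plan attached as attribute `"plan"`.
#' @export
run_scenario <- function(spec, data, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(data, "scenario_data"))
  geno <- data$geno
  out <- list()
  combo <- spec$combo

  pb_ids <- data$pb_pheno$id
  pb_y <- setNames(data$pb_pheno$value, pb_ids)
  sire_ids <- data$sire_pheno$sire_id
  sire_y <- setNames(data$sire_pheno$value, sire_ids)
  cb_ids <- data$cb_pheno$id
  cb_y <- setNames(data$cb_pheno$value, cb_ids)

  # assemble outer splits as a list of list(train, test, rep, fold)
  splits <- list()
  old_y <- NULL  # trn2 generational: averages over OLD crossbred records
  if (spec$split == "kfold") {
    unit_ids <- switch(combo,
                       "trn1-tst1" = pb_ids, "trn1-tst2" = pb_ids,
                       "trn2-tst2" = sire_ids, "trn3-tst2" = cb_ids)
    fams <- if (combo == "trn3-tst2")
      data$pedigree$sire[match(cb_ids, data$pedigree$id)] else NULL
    plan <- build_cv_plan(unit_ids, spec$k, spec$repeats, seed,
                          families = fams)
    for (r in seq_len(spec$repeats))
      for (f in seq_len(spec$k))
        splits[[length(splits) + 1L]] <-
          c(plan$folds[[r]][[f]], list(rep = r, fold = f))
  } else {
    train_pool <- switch(combo,
                         "trn1-tst1" = pb_ids, "trn1-tst2" = pb_ids,
                         "trn2-tst2" = NULL, "trn3-tst2" = cb_ids)
    if (combo %in% c("trn1-tst1")) {
      sp <- split_generational(data$pedigree, pb_ids, spec$n_young)
      splits[[1]] <- list(train = sp$train, test = sp$test, rep = 1, fold = 1)
    } else {
      # OLD/YOUNG defined on the CB records; sire averages recomputed per half
      sp_cb <- split_generational(data$pedigree, cb_ids, spec$n_young)
      young_sires <- sire_averages_of(data, sp_cb$test)
      old_sires <- sire_averages_of(data, sp_cb$train)
      train <- switch(combo,
                      "trn1-tst2" = split_generational(data$pedigree, pb_ids,
                                                       spec$n_young)$train,
                      "trn2-tst2" = setdiff(old_sires$sire_id,
                                            young_sires$sire_id),
                      "trn3-tst2" = sp_cb$train)
      splits[[1]] <- list(train = train, test = young_sires$sire_id,
                          rep = 1, fold = 1)
      sire_y <- setNames(young_sires$value, young_sires$sire_id)
      if (combo == "trn2-tst2") {
        old_y <- setNames(old_sires$value, old_sires$sire_id)
      }
    }
    plan <- splits
  }

  # per-scenario GBLUP machinery: GRM over all animals involved, variance
  # components once per scenario from the training-type records
  if (spec$learner == "gblup") {
    inv_ids <- switch(combo,
                      "trn1-tst1" = pb_ids,
                      "trn1-tst2" = union(pb_ids, sire_ids),
                      "trn2-tst2" = sire_ids,
                      "trn3-tst2" = union(cb_ids, sire_ids))
    if (spec$split == "generational")
      inv_ids <- unique(c(unlist(lapply(splits, `[[`, "train")),
                          unlist(lapply(splits, `[[`, "test")), inv_ids))
    inv_ids <- intersect(inv_ids, rownames(geno))
    G <- compute_grm(geno[inv_ids, , drop = FALSE])
    vc_y <- switch(combo,
                   "trn1-tst1" = pb_y, "trn1-tst2" = pb_y,
                   "trn2-tst2" = if (!is.null(old_y)) old_y else sire_y,
                   "trn3-tst2" = cb_y)
    vc_y <- vc_y[intersect(names(vc_y), inv_ids)]
    vc <- estimate_varcomp(as.numeric(vc_y), G[names(vc_y), names(vc_y)])
  }

  get_train_y <- function(train_ids) {
    switch(combo,
           "trn1-tst1" = pb_y[train_ids], "trn1-tst2" = pb_y[train_ids],
           "trn2-tst2" = if (!is.null(old_y)) old_y[train_ids]
                         else sire_y[train_ids],
           "trn3-tst2" = cb_y[train_ids])
  }
  panel <- if (combo %in% c("trn1-tst1", "trn1-tst2"))
    data$panel_pb else data$panel_sire

  for (s in splits) {
    train_ids <- intersect(s$train, rownames(geno))
    ytr <- get_train_y(train_ids)
    if (combo == "trn1-tst1") {
      test_ids <- s$test
      yte <- pb_y[test_ids]
      groups <- list(ALL = test_ids)
    } else {
      test_ids <- if (combo == "trn1-tst2" && spec$split == "kfold") {
        sire_ids
      } else if (combo == "trn3-tst2" && spec$split == "kfold") {
        # test units are the sires of the held-out CB families
        fam <- unique(data$pedigree$sire[match(s$test, data$pedigree$id)])
        intersect(fam, names(sire_y))
      } else intersect(s$test, names(sire_y))
      yte <- sire_y[test_ids]
      if (combo == "trn1-tst2") {
        po <- partition_in_out(train_ids, test_ids)
        groups <- list(IN = po$in_sires, OUT = po$out_sires)
      } else groups <- list(ALL = test_ids)
    }

    if (spec$learner == "svr") {
      Xtr <- impute_as_matrix(geno[train_ids, panel, drop = FALSE])
      Xte <- impute_as_matrix(geno[test_ids, panel, drop = FALSE])
      mode <- if (spec$testing == "tst2") "self-stats" else "train-stats"
      ok <- apply(Xtr, 2, sd) > 0
      if (mode == "self-stats") ok <- ok & apply(Xte, 2, sd) > 0
      std <- standardize(Xtr[, ok, drop = FALSE], Xte[, ok, drop = FALSE],
                         mode = mode)
      rank_X <- if (spec$rank_on == "all") {
        all_ids <- unique(c(train_ids, test_ids))
        impute_as_matrix(geno[all_ids, panel, drop = FALSE])[, ok, drop = FALSE]
      } else std$train
      rank_y <- if (spec$rank_on == "all") {
        c(ytr, yte)[rownames(rank_X)]
      } else as.numeric(ytr)
      rk <- rank_snps_spearman(rank_X, rank_y)
      preds <- svr_fold_predictions(std$train, as.numeric(ytr), std$other,
                                    rk, spec, derive_seed(seed, s$fold + 100 * s$rep))
      for (kk in names(preds)) {
        pr <- setNames(preds[[kk]], test_ids)
        for (gname in names(groups)) {
          gi <- groups[[gname]]
          if (!length(gi)) next
          out[[length(out) + 1L]] <-
            record_rows(combo, "svr", as.numeric(kk), s$rep, s$fold, gname,
                        gi, as.numeric(yte[gi]), pr[gi])
        }
      }
    } else {
      fit <- gblup(ytr, G, vc = vc)
      pr <- predict(fit, ids = test_ids)
      for (gname in names(groups)) {
        gi <- groups[[gname]]
        if (!length(gi)) next
        out[[length(out) + 1L]] <-
          record_rows(combo, "gblup", NA_real_, s$rep, s$fold, gname,
                      gi, as.numeric(yte[gi]), pr[gi])
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "plan") <- plan
  attr(res, "spec") <- spec
  class(res) <- c("scenario_result", class(res))
  res
}

# Recompute sire averages over a subset of CB records (generational splits
# score the youngest offspring only).
sire_averages_of <- function(data, cb_subset_ids) {
  adj <- data$cb_pheno[data$cb_pheno$id %in% cb_subset_ids, ]
  sa <- sire_average(adj, data$pedigree)
  sa <- sa[sa$sire_id %in% rownames(data$geno), ]
  data.frame(sire_id = sa$sire_id, value = sa$mean, n = sa$n,
             stringsAsFactors = FALSE)
}

impute_as_matrix <- function(x) {
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    m <- col_means_safe(x)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- m[idx[, 2]]
  }
  x
}

#' Summarize scenario predictions into accuracy tables
#'
#' Computes the Spearman correlation per (repeat, fold, group, subset size)
#' over test units, then the median and interquartile range across folds.
#' For single-split generational results the spread comes from
#' [bootstrap_sc()] instead.
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param bootstrap_B resamples for generational results (default 500).
#' @param seed bootstrap seed.
#' @return data frame: scenario, learner, subset_size, group, n_folds,
#'   median_sc, iqr_sc; per-fold correlations in attribute `"per_fold"`.
#' @export
summarize_results <- function(result, bootstrap_B = 500, seed = 1) {
  spec <- attr(result, "spec")
  single <- !is.null(spec) && spec$split == "generational"
  ss <- ifelse(is.na(result$subset_size), "all", result$subset_size)
  key <- interaction(result$learner, ss, result$group,
                     drop = TRUE, lex.order = TRUE)
  rows <- list()
  per_fold <- list()
  for (g in levels(key)) {
    sub <- result[key == g, ]
    if (single) {
      if (nrow(sub) < 3) next
      bs <- bootstrap_sc(sub$observed, sub$predicted, B = bootstrap_B,
                         seed = seed)
      med <- bs$median; iqr <- bs$iqr; scs <- bs$values; nf <- 1L
    } else {
      fk <- interaction(sub$rep, sub$fold, drop = TRUE)
      scs <- vapply(levels(fk), function(ff) {
        ss <- sub[fk == ff, ]
        if (nrow(ss) < 3) return(NA_real_)
        as.numeric(spearman_sc(ss$observed, ss$predicted))
      }, 0)
      scs <- scs[!is.na(scs)]
      if (!length(scs)) next
      s <- summarize_sc(scs)
      med <- unname(s["median"]); iqr <- unname(s["iqr"]); nf <- length(scs)
    }
    rows[[g]] <- data.frame(scenario = sub$scenario[1],
                            learner = sub$learner[1],
                            subset_size = sub$subset_size[1],
                            group = sub$group[1], n_folds = nf,
                            median_sc = med, iqr_sc = iqr,
                            stringsAsFactors = FALSE)
    per_fold[[g]] <- scs
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "per_fold") <- per_fold
  out
}
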