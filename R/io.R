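#' Write and read genotype matrices
#'
#' The primary on-disk dialect is a PLINK-.raw-style whitespace table:
#' header `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#' holding allele doses 0/1/2 with `NA` for missing. A plain CSV dialect
#' (first column `id`, then SNP columns) is also supported. Both round-trip
#' bit-exactly through the corresponding writer.
#'
#' @param geno dose matrix.
#' @param path file path.
#' @param pedigree optional pedigree supplying FID/PAT/MAT/SEX columns.
#' @param dialect `"plink_raw"` or `"csv"`.
#' @return `write_genotypes` returns the path invisibly; `read_genotypes`
#'   returns the dose matrix.
#' @export
write_genotypes <- function(geno, path, pedigree = NULL,
                            dialect = c("plink_raw", "csv")) {
  check_geno(geno)
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(id = rownames(geno), geno, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ids <- rownames(geno)
  idx <- if (!is.null(pedigree)) match(ids, pedigree$id) else rep(NA, length(ids))
  fam <- data.frame(FID = ifelse(is.na(idx), "0", pedigree$line[idx]),
                    IID = ids,
                    PAT = if (!is.null(pedigree))
                      ifelse(is.na(pedigree$sire[idx]), "0", pedigree$sire[idx])
                    else "0",
                    MAT = if (!is.null(pedigree))
                      ifelse(is.na(pedigree$dam[idx]), "0", pedigree$dam[idx])
                    else "0",
                    SEX = if (!is.null(pedigree))
                      ifelse(pedigree$sex[idx] == "M", 1L, 2L) else 0L,
                    PHENOTYPE = -9,
                    stringsAsFactors = FALSE)
  df <- cbind(fam, as.data.frame(geno, check.names = FALSE))
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, dialect = c("plink_raw", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  if (dialect == "csv") {
    df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    meta_n <- 1L
    ids <- as.character(df[[1]])
  } else {
    df <- read.table(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(names(df)[seq_len(6)], need))
      stopf("not a PLINK-raw-style file: header must start with %s",
            paste(need, collapse = " "))
    meta_n <- 6L
    ids <- as.character(df$IID)
  }
  snp_cols <- names(df)[-seq_len(meta_n)]
  if (!length(snp_cols)) stopf("no SNP columns found in %s", path)
  g <- as.matrix(df[snp_cols])
  bad <- which(!(is.na(g) | g %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stopf("invalid dose '%s' at data row %d, SNP %s", g[bad[1, , drop = FALSE]],
          bad[1, 1], snp_cols[bad[1, 2]])
  storage.mode(g) <- "integer"
  rownames(g) <- ids
  check_geno(g)
}

#' Write and read pedigree tables
#'
#' CSV with columns id, sire, dam, line, sex, generation; unknown parents
#' are empty/NA. Reading validates: duplicate ids are an error; a parent id
#' absent from the table is set to unknown with a warning; a pedigree cycle
#' is an error.
#'
#' @param pedigree pedigree data frame.
#' @param path file path.
#' @return `write_pedigree` the path invisibly; `read_pedigree` the
#'   validated data frame.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stopf("pedigree file not found: %s", path)
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stopf("pedigree needs columns %s", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  if (anyDuplicated(df$id))
    stopf("duplicate pedigree id(s): %s",
          paste(utils::head(unique(df$id[duplicated(df$id)]), 5), collapse = ", "))
  for (col in c("sire", "dam")) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% df$id)
    if (any(bad)) {
      warnf("%d %s id(s) not in pedigree; set to unknown", sum(bad), col)
      df[[col]][bad] <- NA
    }
  }
  assign_generations(df)  # errors on cycles
  df
}

#' Write and read raw phenotype tables
#'
#' CSV of raw performance-test records. Reading validates that weights are
#' positive and durations positive.
#'
#' @param records phenotype data frame.
#' @param path file path.
#' @return `write_phenotypes` the path invisibly; `read_phenotypes` the
#'   validated data frame.
#' @export
write_phenotypes <- function(records, path) {
  write.table(records, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stopf("duplicate phenotype record id(s)")
  num <- intersect(c("dfi", "adg", "backfat", "w_start", "w_end",
                     "age_start", "duration"), names(df))
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  if ("duration" %in% names(df) && any(df$duration <= 0, na.rm = TRUE))
    stopf("non-positive test duration in phenotype file")
  if (any(unlist(df[intersect(c("w_start", "w_end"), names(df))]) <= 0,
          na.rm = TRUE))
    stopf("non-positive weight in phenotype file")
  df
}

run_config_schema <- c("sim", "qc", "learner", "scenarios", "traits", "seed")

#' Read a pipeline run configuration
#'
#' JSON with top-level keys `sim` (overrides for [sim_config()]), `qc`
#' (thresholds for [qc_pipeline()]), `learner` (SVR grids/epsilon),
#' `scenarios` (list of scenario descriptions: training, testing, learner,
#' optionally subset_sizes, split, k, repeats), `traits` and `seed`.
#' Unknown keys are an error (fail-fast).
#'
#' @param path JSON file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_schema)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$traits <- cfg$traits %||% c("rfi", "adg")
  structure(cfg, class = "run_config")
}

#' Prepare evaluation bundles from a simulated dataset
#'
#' Runs phenotype preparation for the three data subsets (individual
#' purebred records, CB-offspring-of-sire records, individual crossbred
#' records), the genotype QC cascade with per-subset feature panels, and
#' assembles one [scenario_data()] bundle per trait.
#'
#' @param dataset a [simulate_dataset()] result (or an equivalent list with
#'   `pedigree`, `geno`, `phenotypes`).
#' @param traits traits to bundle (default RFI and ADG).
#' @param qc_args named list of overrides for [qc_pipeline()] thresholds.
#' @return list with `bundles` (named by trait), `qc`, and `preps`.
#' @export
prepare_bundles <- function(dataset, traits = c("rfi", "adg"),
                            qc_args = list()) {
  ped <- dataset$pedigree
  phe <- dataset$phenotypes
  pb_rec <- phe[phe$line == "terminal", ]
  cb_rec <- phe[phe$line == "CB", ]
  prep_pb <- prep_phenotypes(pb_rec, ped, "pb")
  prep_cbs <- prep_phenotypes(cb_rec, ped, "cb_sire")
  prep_cb <- prep_phenotypes(cb_rec, ped, "cb")
  sire_ids <- unique(ped$sire[ped$line == "CB"])
  qc <- do.call(qc_pipeline,
                c(list(geno = dataset$geno, pedigree = ped,
                       subsets = list(pb = prep_pb$adjusted$id,
                                      sire = sire_ids)),
                  qc_args))
  bundles <- lapply(traits, function(trait) {
    scenario_data(
      geno = qc$geno, pedigree = ped,
      pb_pheno = data.frame(id = prep_pb$adjusted$id,
                            value = prep_pb$adjusted[[trait]]),
      cb_pheno = data.frame(id = prep_cb$adjusted$id,
                            value = prep_cb$adjusted[[trait]]),
      sire_pheno = data.frame(sire_id = prep_cbs$sire_means$sire_id,
                              value = prep_cbs$sire_means[[trait]],
                              n = prep_cbs$sire_means$n),
      panel_pb = qc$panels$pb, panel_sire = qc$panels$sire)
  })
  names(bundles) <- traits
  list(bundles = bundles, qc = qc,
       preps = list(pb = prep_pb, cb_sire = prep_cbs, cb = prep_cb))
}

#' Run the complete pipeline on a configuration
#'
#' Simulates a crossbreeding dataset, prepares adjusted phenotypes for the
#' three data subsets, runs the genotype QC cascade, executes the requested
#' evaluation scenarios for each trait, and writes all artifacts to
#' `out_dir`: pedigree/phenotype/genotype files, a QC report, a tidy
#' results TSV, an evaluation-summary JSON and a reproducibility manifest.
#' Re-running with the same configuration and seed reproduces every output
#' byte for byte (no timestamps are written).
#'
#' @param config a `run_config` (see [read_run_config()]) or path to one.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when not NULL.
#' @return invisibly, a list with the in-memory results (dataset, qc,
#'   bundles, results, summaries).
#' @export
full_run <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  dataset <- simulate_dataset(scfg)
  ped <- dataset$pedigree
  phe <- dataset$phenotypes

  write_pedigree(ped, file.path(out_dir, "pedigree.csv"))
  write_phenotypes(phe, file.path(out_dir, "phenotypes.csv"))
  write_genotypes(dataset$geno, file.path(out_dir, "genotypes.raw"), ped)

  prep <- prepare_bundles(dataset, traits = config$traits,
                          qc_args = config$qc %||% list())
  qc <- prep$qc
  prep_pb <- prep$preps$pb; prep_cbs <- prep$preps$cb_sire
  prep_cb <- prep$preps$cb
  qc_json <- lapply(qc$reports, function(r)
    list(rule = r$rule, axis = r$axis, dropped = r$n_dropped,
         retained = r$n_retained))
  jsonlite::write_json(qc_json, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  scen_list <- config$scenarios
  if (is.null(scen_list))
    scen_list <- list(list(training = "trn1", testing = "tst1",
                           learner = "svr"))
  if (is.data.frame(scen_list))
    scen_list <- lapply(seq_len(nrow(scen_list)), function(i)
      as.list(scen_list[i, , drop = FALSE]))

  learner_cfg <- config$learner %||% list()
  all_res <- list()
  summaries <- list()
  for (trait in config$traits) {
    bundle <- prep$bundles[[trait]]
    for (sc in scen_list) {
      sp_args <- lapply(sc, function(v) if (is.list(v)) unlist(v) else v)
      # JSON data-frame rows carry NULL/NA for keys other scenarios set
      sp_args <- sp_args[!vapply(sp_args, function(v)
        is.null(v) || length(v) == 0 ||
          (length(v) == 1 && !is.list(v) && is.na(v)), TRUE)]
      for (nm in c("C_grid", "gamma_grid", "epsilon", "inner_k"))
        if (!is.null(learner_cfg[[nm]]) && is.null(sp_args[[nm]]))
          sp_args[[nm]] <- learner_cfg[[nm]]
      if (!is.null(sp_args$subset_sizes))
        sp_args$subset_sizes <- as.numeric(unlist(sp_args$subset_sizes))
      sp <- do.call(scenario_spec, sp_args)
      res <- run_scenario(sp, bundle, seed = derive_seed(seed, 7L))
      res$trait <- trait
      key <- sprintf("%s_%s_%s", trait, sp$combo, sp$learner)
      all_res[[key]] <- res
      summ <- summarize_results(res, seed = derive_seed(seed, 9L))
      summ$trait <- trait
      summaries[[key]] <- summ
    }
  }
  res_df <- do.call(rbind, c(all_res, list(make.row.names = FALSE)))
  write.table(res_df, file.path(out_dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ_df <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  jsonlite::write_json(summ_df, file.path(out_dir, "summary.json"),
                       pretty = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("crossgp")),
    seed = seed,
    config = unclass(config),
    outputs = c("pedigree.csv", "phenotypes.csv", "genotypes.raw",
                "qc_report.json", "results.tsv", "summary.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = dataset, qc = qc, results = res_df,
                 summaries = summ_df,
                 preps = list(pb = prep_pb, cb_sire = prep_cbs, cb = prep_cb)))
}
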