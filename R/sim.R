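#' Simulation configuration for a three-way crossbreeding population
#'
#' Builds the configuration object consumed by [simulate_population()] and
#' [simulate_dataset()]. The defaults describe a desk-scale analogue of a
#' commercial pig crossbreeding scheme: a terminal sire line bred for several
#' non-overlapping generations, two maternal lines whose cross produces F1
#' sows, and three-way crossbred (CB) growing-finishing pigs sired by
#' terminal-line boars. Feed efficiency (residual feed intake, RFI) and
#' growth rate (average daily gain, ADG) are controlled by shared QTL with
#' additive and dominance action; line-context deviations of the additive
#' effects lower the purebred-crossbred genetic correlation (rPB,CB) below 1.
#'
#' @param n_founders_per_line founders in each of the three pure lines (and
#'   cohort size of later terminal-line generations).
#' @param n_snps number of SNPs on the simulated chip.
#' @param n_qtl number of QTL (a subset of the SNPs).
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param n_generations_pb terminal-line generations bred after the founders.
#' @param offspring_per_sire CB offspring produced per CB-mated sire
#'   (10 is a typical median progeny-group size for sire-average records).
#' @param n_cb_sires terminal-line boars mated to F1 sows; 0 disables the
#'   crossbred tier entirely.
#' @param n_f1_sows F1 sows available as CB dams.
#' @param h2_target named numeric, target narrow-sense heritability per trait.
#' @param dominance_degree mean |d/a| of dominance to additive effects.
#' @param line_context_sd SD of line-context additive deviations, in units of
#'   the additive-effect SD; larger values lower rPB,CB (see
#'   [calibrate_line_context()]).
#' @param block_size,block_rho founder-haplotype LD block length and
#'   within-block latent correlation (gives correlation pruning real work).
#' @param env list of environment-effect settings: `farm_batch_sd` (g/day SD
#'   of farm-by-batch shifts), `sex_shift` (g/day added for males),
#'   `age_slope`, `duration_slope` (g/day per day of age at start / test
#'   duration), `n_batches` (batches per farm).
#' @param trait_sd named numeric, phenotypic SD (g/day) of the genetic plus
#'   residual part per trait.
#' @param dfi_coef planted linear coefficients building daily feed intake
#'   from ADG, backfat and metabolic weight.
#' @param missing_rate per-cell genotype missingness rate.
#' @param mendel_error_rate per offspring-locus rate of planted
#'   opposite-homozygote Mendelian errors.
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders_per_line = 100,
                       n_snps = 1200,
                       n_qtl = 150,
                       maf_range = c(0.05, 0.5),
                       n_generations_pb = 4,
                       offspring_per_sire = 10,
                       n_cb_sires = 50,
                       n_f1_sows = 120,
                       h2_target = c(rfi = 0.35, adg = 0.30),
                       dominance_degree = 0.2,
                       line_context_sd = 0,
                       block_size = 8,
                       block_rho = 0.99,
                       env = list(),
                       trait_sd = c(rfi = 160, adg = 110),
                       dfi_coef = c(intercept = 400, adg = 1.6,
                                    backfat = 20, mw = 9),
                       missing_rate = 0.01,
                       mendel_error_rate = 0.001,
                       seed = 1L) {
  env_def <- list(farm_batch_sd = 25, sex_shift = 40, age_slope = -1.5,
                  duration_slope = 1.0, n_batches = 4)
  unknown <- setdiff(names(env), names(env_def))
  if (length(unknown)) stopf("unknown env settings: %s",
                             paste(unknown, collapse = ", "))
  env_def[names(env)] <- env
  cfg <- list(n_founders_per_line = as.integer(n_founders_per_line),
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              maf_range = as.numeric(maf_range),
              n_generations_pb = as.integer(n_generations_pb),
              offspring_per_sire = as.integer(offspring_per_sire),
              n_cb_sires = as.integer(n_cb_sires),
              n_f1_sows = as.integer(n_f1_sows),
              h2_target = h2_target,
              dominance_degree = dominance_degree,
              line_context_sd = line_context_sd,
              block_size = as.integer(block_size), block_rho = block_rho,
              env = env_def, trait_sd = trait_sd, dfi_coef = dfi_coef,
              missing_rate = missing_rate,
              mendel_error_rate = mendel_error_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_founders_per_line <= 0 || n_snps <= 0 || n_qtl <= 0 ||
        offspring_per_sire <= 0 || n_generations_pb < 0)
      stopf("all population counts must be positive")
    if (n_cb_sires < 0) stopf("n_cb_sires must be >= 0")
    if (n_cb_sires > 0 && n_f1_sows <= 0)
      stopf("impossible mating structure: CB offspring requested but no F1 sows")
    if (n_qtl > n_snps) stopf("n_qtl cannot exceed n_snps")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stopf("maf_range must lie within (0, 0.5]")
    if (any(h2_target < 0 | h2_target > 1))
      stopf("h2_target values must be in [0, 1]")
    if (is.null(names(h2_target)) || !setequal(names(h2_target), names(trait_sd)))
      stopf("h2_target and trait_sd must be named by the same traits")
    if (dominance_degree < 0 || line_context_sd < 0)
      stopf("dominance_degree and line_context_sd must be >= 0")
    if (missing_rate < 0 || missing_rate > 1 ||
        mendel_error_rate < 0 || mendel_error_rate > 1)
      stopf("corruption rates must be in [0, 1]")
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Three-way crossbreeding simulation config\n")
  cat(sprintf("  lines: %d founders x 3; terminal generations: %d\n",
              x$n_founders_per_line, x$n_generations_pb))
  cat(sprintf("  CB tier: %d sires x %d offspring, %d F1 sows\n",
              x$n_cb_sires, x$offspring_per_sire, x$n_f1_sows))
  cat(sprintf("  genome: %d SNPs (%d QTL), MAF in [%.2f, %.2f], LD blocks %d @ rho=%.2f\n",
              x$n_snps, x$n_qtl, x$maf_range[1], x$maf_range[2],
              x$block_size, x$block_rho))
  cat(sprintf("  h2 targets: %s; dominance %.2f; line-context SD %.2f\n",
              paste(sprintf("%s=%.2f", names(x$h2_target), x$h2_target),
                    collapse = ", "),
              x$dominance_degree, x$line_context_sd))
  invisible(x)
}

# Founder haplotypes with block-AR(1) LD via a Gaussian copula.
# Returns an n_hap x n_snps 0/1 matrix.
founder_haplotypes <- function(n_hap, p, block_size, block_rho) {
  m <- length(p)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  if (block_rho > 0 && block_size > 1) {
    w <- sqrt(1 - block_rho^2)
    for (j in seq_len(m)[-1]) {
      if ((j - 1) %% block_size != 0)  # block boundary resets the chain
        z[, j] <- block_rho * z[, j - 1] + w * z[, j]
    }
  }
  thr <- stats::qnorm(p)
  hap <- matrix(0L, n_hap, m)
  hap[sweep(z, 2, thr, "<")] <- 1L
  hap
}

# One uniformly chosen allele per parent per locus (gene dropping,
# no linkage in transmission).
transmit <- function(h1, h2) {
  pick <- runif(length(h1)) < 0.5
  ifelse(pick, h1, h2)
}

#' Simulate a pedigreed purebred and three-way crossbred population
#'
#' Generates founder haplotypes for a terminal sire line and two maternal
#' lines, breeds the terminal line by random mating for
#' `n_generations_pb` generations, crosses the maternal lines into F1 sows,
#' and mates terminal-line boars to F1 sows to produce three-way CB
#' offspring. Descendant genotypes are produced by gene dropping: each child
#' receives one uniformly chosen allele per parent per locus. QTL positions
#' and effects (additive, dominance, line-context deviations) are drawn here
#' as well.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_population`: a list with elements
#'   `pedigree` (data frame: id, sire, dam, line, sex, generation),
#'   `geno` (dose matrix, no missing values), `qtl` (QTL model), and
#'   `haplo` (list of paternal/maternal haplotype matrices, used by
#'   transmission checks).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  nf <- config$n_founders_per_line
  snp_ids <- sprintf("snp%05d", seq_len(m))
  p <- runif(m, config$maf_range[1], config$maf_range[2])

  n_cb <- if (config$n_cb_sires > 0) config$n_cb_sires * config$offspring_per_sire else 0L
  n_f1 <- if (config$n_cb_sires > 0) config$n_f1_sows else 0L
  n_total <- 3L * nf + nf * config$n_generations_pb + n_f1 + n_cb
  ids <- character(n_total); sire <- rep(NA_character_, n_total)
  dam <- rep(NA_character_, n_total)
  line <- character(n_total); sex <- character(n_total)
  gen <- integer(n_total)
  H1 <- matrix(0L, n_total, m)  # paternal haplotypes, rows = individuals
  H2 <- matrix(0L, n_total, m)  # maternal haplotypes
  n_cur <- 0L

  add_ind <- function(id, s, d, ln, sx, g, h1, h2) {
    n_cur <<- n_cur + 1L
    ids[n_cur] <<- id; sire[n_cur] <<- s; dam[n_cur] <<- d
    line[n_cur] <<- ln; sex[n_cur] <<- sx; gen[n_cur] <<- g
    H1[n_cur, ] <<- h1; H2[n_cur, ] <<- h2
  }

  # founders of the three pure lines
  founder_line <- function(ln, prefix) {
    h1 <- founder_haplotypes(nf, p, config$block_size, config$block_rho)
    h2 <- founder_haplotypes(nf, p, config$block_size, config$block_rho)
    sx <- rep(c("M", "F"), length.out = nf)
    for (i in seq_len(nf))
      add_ind(sprintf("%s_g0_%04d", prefix, i), NA_character_, NA_character_,
              ln, sx[i], 0L, h1[i, ], h2[i, ])
  }
  founder_line("terminal", "ter")
  founder_line("maternal1", "m1")
  founder_line("maternal2", "m2")

  idx_of <- function(id) match(id, ids)
  breed <- function(s_id, d_id) {
    si <- idx_of(s_id); di <- idx_of(d_id)
    list(h1 = transmit(H1[si, ], H2[si, ]), h2 = transmit(H1[di, ], H2[di, ]))
  }

  # terminal line: discrete generations, random mating
  for (g in seq_len(config$n_generations_pb)) {
    prev <- ids[line == "terminal" & gen == g - 1L]
    males <- prev[sex[match(prev, ids)] == "M"]
    females <- prev[sex[match(prev, ids)] == "F"]
    if (!length(males) || !length(females))
      stopf("impossible mating structure: terminal generation %d lacks a sex", g - 1L)
    sx <- rep(c("M", "F"), length.out = nf)
    s_pick <- sample(males, nf, replace = TRUE)
    d_pick <- sample(females, nf, replace = TRUE)
    for (i in seq_len(nf)) {
      hh <- breed(s_pick[i], d_pick[i])
      add_ind(sprintf("ter_g%d_%04d", g, i), s_pick[i], d_pick[i],
              "terminal", sx[i], g, hh$h1, hh$h2)
    }
  }

  if (config$n_cb_sires > 0) {
    # F1 sows: maternal1 sires x maternal2 dams
    m1_males <- ids[line == "maternal1" & sex == "M"]
    m2_females <- ids[line == "maternal2" & sex == "F"]
    if (!length(m1_males) || !length(m2_females))
      stopf("impossible mating structure: maternal lines lack breeding animals")
    s_pick <- sample(m1_males, config$n_f1_sows, replace = TRUE)
    d_pick <- sample(m2_females, config$n_f1_sows, replace = TRUE)
    for (i in seq_len(config$n_f1_sows)) {
      hh <- breed(s_pick[i], d_pick[i])
      add_ind(sprintf("f1_%04d", i), s_pick[i], d_pick[i],
              "F1sow", "F", 1L, hh$h1, hh$h2)
    }

    # CB: terminal boars (recent generations) x F1 sows
    recent <- max(0L, config$n_generations_pb - 2L):config$n_generations_pb
    cand <- ids[line == "terminal" & sex == "M" & gen %in% recent]
    if (length(cand) < config$n_cb_sires)
      stopf("impossible mating structure: only %d terminal boars available for %d CB sires",
            length(cand), config$n_cb_sires)
    cb_sires <- sample(cand, config$n_cb_sires)
    k <- 0L
    for (s_id in cb_sires) {
      sg <- gen[idx_of(s_id)]
      for (o in seq_len(config$offspring_per_sire)) {
        k <- k + 1L
        d_id <- sample(ids[line == "F1sow"], 1L)
        hh <- breed(s_id, d_id)
        add_ind(sprintf("cb_%05d", k), s_id, d_id, "CB",
                sample(c("M", "F"), 1L, prob = c(0.7, 0.3)), sg + 1L,
                hh$h1, hh$h2)
      }
    }
  }

  ids <- ids[seq_len(n_cur)]; sire <- sire[seq_len(n_cur)]
  dam <- dam[seq_len(n_cur)]; line <- line[seq_len(n_cur)]
  sex <- sex[seq_len(n_cur)]; gen <- gen[seq_len(n_cur)]
  H1 <- H1[seq_len(n_cur), , drop = FALSE]
  H2 <- H2[seq_len(n_cur), , drop = FALSE]
  rownames(H1) <- rownames(H2) <- ids
  geno <- H1 + H2
  storage.mode(geno) <- "integer"
  colnames(geno) <- snp_ids

  pedigree <- data.frame(id = ids, sire = sire, dam = dam, line = line,
                         sex = sex, generation = gen,
                         stringsAsFactors = FALSE)

  # QTL model: shared loci, per-trait additive/dominance/line-context effects
  traits <- names(config$h2_target)
  qtl_idx <- sort(sample(m, config$n_qtl))
  a <- matrix(rnorm(config$n_qtl * length(traits)), config$n_qtl,
              dimnames = list(snp_ids[qtl_idx], traits))
  # mean |d/a| = dominance_degree (half-normal scaled to unit mean)
  d <- config$dominance_degree * abs(a) * sqrt(pi / 2) *
    matrix(rnorm(config$n_qtl * length(traits)), config$n_qtl)
  dimnames(d) <- dimnames(a)
  b <- config$line_context_sd *
    matrix(rnorm(config$n_qtl * length(traits)), config$n_qtl)
  dimnames(b) <- dimnames(a)
  qtl <- structure(list(qtl_ids = snp_ids[qtl_idx], additive = a,
                        dominance = d, line_dev = b, traits = traits,
                        founder_freq = p[qtl_idx]),
                   class = "qtl_model")

  structure(list(pedigree = pedigree, geno = geno, qtl = qtl,
                 haplo = list(paternal = H1, maternal = H2),
                 founder_freq = setNames(p, snp_ids), config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$pedigree$line)
  cat("Simulated crossbreeding population\n")
  cat(sprintf("  %d individuals (%s), %d SNPs, %d QTL\n",
              nrow(x$pedigree),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              ncol(x$geno), length(x$qtl$qtl_ids)))
  invisible(x)
}

#' True genetic values in purebred and crossbred context
#'
#' For each individual and trait, computes the genotypic value under the
#' purebred-context QTL effects (additive `a`, dominance `d`) and under the
#' crossbred-context effects (`a` plus the line-context deviation). The
#' correlation between the two columns across individuals is the realized
#' purebred-crossbred genetic correlation of the simulation
#' (see [realized_rpbcb()]).
#'
#' @param pedigree pedigree data frame (used for id order).
#' @param geno dose matrix covering the QTL loci.
#' @param qtl QTL model from [simulate_population()].
#' @return object of class `genetic_values`: list with matrices `pb` and
#'   `cb` (individuals x traits).
#' @export
genetic_values <- function(pedigree, geno, qtl) {
  miss_ids <- setdiff(qtl$qtl_ids, colnames(geno))
  if (length(miss_ids))
    stopf("QTL loci absent from genotype matrix: %s",
          paste(utils::head(miss_ids, 5), collapse = ", "))
  x <- geno[pedigree$id, qtl$qtl_ids, drop = FALSE]
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    n_imp <- sum(is.na(x))
    m <- col_means_safe(x)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- m[idx[, 2]]
    message(sprintf("genetic_values: imputed %d missing QTL doses to locus means", n_imp))
  }
  xc <- x - 1                      # additive coding -1/0/+1
  het <- (x == 1) * 1              # heterozygosity indicator
  pb <- xc %*% qtl$additive + het %*% qtl$dominance
  cb <- xc %*% (qtl$additive + qtl$line_dev) + het %*% qtl$dominance
  dimnames(pb) <- dimnames(cb) <- list(pedigree$id, qtl$traits)
  structure(list(pb = pb, cb = cb), class = "genetic_values")
}

#' Realized purebred-crossbred genetic correlation
#'
#' @param gv a [genetic_values()] object.
#' @param trait trait name, or NULL for the mean over traits.
#' @return correlation between PB-context and CB-context genetic values.
#' @export
realized_rpbcb <- function(gv, trait = NULL) {
  traits <- if (is.null(trait)) colnames(gv$pb) else trait
  mean(vapply(traits, function(tr) cor(gv$pb[, tr], gv$cb[, tr]), 0))
}

#' Calibrate the line-context SD to a target rPB,CB
#'
#' The purebred-crossbred genetic correlation is an emergent property of the
#' simulated QTL effects; this helper performs a one-dimensional search on
#' `line_context_sd` so that the expected correlation between PB-context and
#' CB-context genetic values matches `target_r`. With additive variance
#' sigma_g^2 and unit-SD deviations contributing sigma_d^2, the expected
#' correlation at deviation scale s is sigma_g / sqrt(sigma_g^2 + s^2
#' sigma_d^2); both variances are estimated from a reference simulation
#' (averaging several deviation draws) and the equation is solved for s.
#'
#' @param config a [sim_config()]; its seed anchors the reference simulation.
#' @param target_r desired rPB,CB (the literature average for pig feed
#'   efficiency and growth traits is 0.66).
#' @param n_draws unit-deviation draws used to estimate sigma_d^2.
#' @return the config with `line_context_sd` set to the calibrated value.
#' @export
calibrate_line_context <- function(config, target_r = 0.66, n_draws = 8) {
  stopifnot(inherits(config, "sim_config"), target_r > 0, target_r <= 1)
  if (target_r == 1) { config$line_context_sd <- 0; return(config) }
  ref <- config
  ref$line_context_sd <- 0
  pop <- simulate_population(ref)
  gv <- genetic_values(pop$pedigree, pop$geno, pop$qtl)
  x <- pop$geno[, pop$qtl$qtl_ids, drop = FALSE]
  xc <- x - 1
  set.seed(derive_seed(config$seed, 77L))
  traits <- pop$qtl$traits
  ratio <- vapply(traits, function(tr) {
    s2g <- var(gv$pb[, tr])
    s2d <- mean(vapply(seq_len(n_draws), function(k) {
      var(as.vector(xc %*% rnorm(ncol(xc))))
    }, 0))
    sqrt(s2g / s2d)
  }, 0)
  config$line_context_sd <- mean(ratio) * sqrt(1 / target_r^2 - 1)
  config
}

#' Simulate raw phenotype records
#'
#' Produces one raw performance-test record per phenotyped animal
#' (terminal-line boars and all CB pigs): daily feed intake (g/day), ADG
#' (g/day), backfat (mm), start/end test weights (kg), age at start and test
#' duration (days), farm, batch and sex. ADG is built from the
#' context-appropriate genetic value (PB context for purebreds, CB context
#' for crossbreds) scaled so its narrow-sense heritability matches
#' `h2_target`, plus age/duration covariate effects, a farm-by-batch shift,
#' a sex shift and residual noise. DFI is a planted linear function of ADG,
#' backfat and metabolic weight plus an independent true-RFI component
#' carrying its own genetic and residual terms. The planted truth (shifts,
#' coefficients, genetic values, true RFI) is attached as attribute
#' `"truth"` for downstream checks.
#'
#' @param pedigree pedigree data frame.
#' @param gv [genetic_values()] for the same individuals.
#' @param config the [sim_config()].
#' @param seed RNG seed (defaults to a seed derived from the config seed).
#' @return data frame of raw phenotype records.
#' @export
simulate_phenotypes <- function(pedigree, gv, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% derive_seed(config$seed, 11L))
  keep <- with(pedigree, (line == "terminal" & sex == "M") | line == "CB")
  ped <- pedigree[keep, , drop = FALSE]
  n <- nrow(ped)
  if (n == 0) stopf("no phenotypable animals (terminal boars or CB) in pedigree")
  is_cb <- ped$line == "CB"
  env <- config$env

  farm <- sample(c("farm1", "farm2"), n, replace = TRUE)
  batch <- sprintf("b%02d", sample.int(env$n_batches, n, replace = TRUE))
  fb <- interaction(farm, batch, drop = TRUE)
  fb_shift_adg <- setNames(rnorm(nlevels(fb), 0, env$farm_batch_sd), levels(fb))
  fb_shift_dfi <- setNames(rnorm(nlevels(fb), 0, 1.5 * env$farm_batch_sd), levels(fb))

  age_start <- pmin(pmax(round(rnorm(n, 68, 12)), 40), 130)
  duration <- pmin(pmax(round(rnorm(n, 88, 14)), 40), 150)

  scale_gv <- function(raw, trait) {
    # empirical scaling to the target genetic SD within phenotyped animals
    sdg <- config$trait_sd[trait] * sqrt(config$h2_target[trait])
    s <- sd(raw)
    if (s < 1e-12) return(rep(0, length(raw)))
    (raw - mean(raw)) * sdg / s
  }
  gv_use <- function(trait) {
    raw <- ifelse(is_cb, gv$cb[ped$id, trait], gv$pb[ped$id, trait])
    scale_gv(raw, trait)
  }
  g_adg <- gv_use("adg")
  g_rfi <- gv_use("rfi")
  e_adg <- rnorm(n, 0, config$trait_sd["adg"] * sqrt(1 - config$h2_target["adg"]))
  e_rfi <- rnorm(n, 0, config$trait_sd["rfi"] * sqrt(1 - config$h2_target["rfi"]))

  adg_mean <- ifelse(is_cb, 880, 1112)
  adg <- adg_mean + g_adg + e_adg +
    env$age_slope * (age_start - 68) + env$duration_slope * (duration - 88) +
    fb_shift_adg[as.character(fb)] + env$sex_shift * (ped$sex == "M" & is_cb)

  w_start <- pmax(rnorm(n, ifelse(is_cb, 25, 31), 3), 8)
  w_end <- pmax(w_start + adg * duration / 1000 + rnorm(n, 0, 3), w_start + 5)
  backfat <- pmax(12 + 0.01 * (adg - adg_mean) + rnorm(n, 0, 2), 2)
  mw <- metabolic_weight(w_start, w_end)

  rfi_true <- g_rfi + e_rfi
  cf <- config$dfi_coef
  dfi <- cf["intercept"] + cf["adg"] * adg + cf["backfat"] * backfat +
    cf["mw"] * mw + rfi_true + fb_shift_dfi[as.character(fb)] +
    2 * env$age_slope * (age_start - 68) + 2 * env$duration_slope * (duration - 88)

  rec <- data.frame(id = ped$id, dfi = as.numeric(dfi), adg = as.numeric(adg),
                    backfat = backfat, w_start = w_start, w_end = w_end,
                    age_start = age_start, duration = duration,
                    farm = farm, batch = batch, sex = ped$sex,
                    line = ped$line, stringsAsFactors = FALSE)
  attr(rec, "truth") <- list(fb_shift_adg = fb_shift_adg,
                             fb_shift_dfi = fb_shift_dfi,
                             dfi_coef = cf, rfi_true = as.numeric(rfi_true),
                             g_adg = g_adg, g_rfi = g_rfi,
                             e_rfi = as.numeric(e_rfi))
  rec
}

#' Plant genotype missingness and Mendelian errors
#'
#' Corrupts a clean genotype matrix for quality-control testing: each cell
#' is set missing independently with probability `missing_rate`; then, at
#' sampled still-observed offspring loci where a genotyped parent is
#' homozygous, the offspring dose is flipped to the opposite homozygote
#' (an impossible transmission). Missingness is applied first so every
#' planted Mendelian defect remains observable by [mendel_check()].
#'
#' @param geno clean dose matrix.
#' @param pedigree pedigree data frame linking offspring to parents.
#' @param missing_rate per-cell missingness probability.
#' @param mendel_error_rate per offspring-locus defect probability.
#' @param seed RNG seed.
#' @return list with elements `geno` (corrupted matrix) and `log` (list:
#'   `n_missing`, and `mendel`, a data frame of planted defects with columns
#'   id, parent, snp, old, new).
#' @export
corrupt_genotypes <- function(geno, pedigree, missing_rate = 0,
                              mendel_error_rate = 0, seed = 1L) {
  check_geno(geno)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  out <- geno
  log <- list(n_missing = 0L,
              mendel = data.frame(id = character(0), parent = character(0),
                                  snp = character(0), old = integer(0),
                                  new = integer(0), stringsAsFactors = FALSE))
  if (missing_rate == 0 && mendel_error_rate == 0)
    return(list(geno = out, log = log))
  set.seed(seed)
  if (missing_rate > 0) {
    mask <- matrix(runif(length(out)) < missing_rate, nrow(out))
    out[mask] <- NA_integer_
    log$n_missing <- sum(mask)
  }
  if (mendel_error_rate > 0) {
    ped <- pedigree[pedigree$id %in% rownames(out), , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      parents <- c(ped$sire[i], ped$dam[i])
      parents <- parents[!is.na(parents) & parents %in% rownames(out)]
      if (!length(parents)) next
      par <- if (length(parents) == 1) parents else sample(parents, 1L)
      pd <- out[par, ]
      ok <- which(!is.na(pd) & pd != 1L & !is.na(out[id, ]))
      if (!length(ok)) next
      hit <- ok[runif(length(ok)) < mendel_error_rate]
      if (!length(hit)) next
      old <- out[id, hit]
      new <- 2L - pd[hit]          # opposite homozygote of the parent
      out[id, hit] <- new
      recs[[length(recs) + 1L]] <-
        data.frame(id = id, parent = par, snp = colnames(out)[hit],
                   old = as.integer(old), new = as.integer(new),
                   stringsAsFactors = FALSE)
    }
    if (length(recs)) log$mendel <- do.call(rbind, recs)
  }
  list(geno = out, log = log)
}

#' Simulate a complete crossbreeding dataset
#'
#' Convenience wrapper running [simulate_population()], [genetic_values()],
#' [simulate_phenotypes()] and [corrupt_genotypes()] under one seed.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset`: list with `config`, `pedigree`,
#'   `geno` (corrupted), `geno_clean`, `qtl`, `gv`, `phenotypes`, `defects`.
#' @export
simulate_dataset <- function(config) {
  pop <- simulate_population(config)
  gv <- genetic_values(pop$pedigree, pop$geno, pop$qtl)
  phe <- simulate_phenotypes(pop$pedigree, gv, config)
  cor_res <- corrupt_genotypes(pop$geno, pop$pedigree,
                               missing_rate = config$missing_rate,
                               mendel_error_rate = config$mendel_error_rate,
                               seed = derive_seed(config$seed, 23L))
  structure(list(config = config, pedigree = pop$pedigree,
                 geno = cor_res$geno, geno_clean = pop$geno, qtl = pop$qtl,
                 gv = gv, phenotypes = phe, defects = cor_res$log,
                 haplo = pop$haplo),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  tab <- table(x$pedigree$line)
  cat("Simulated crossbreeding dataset\n")
  cat(sprintf("  %d animals (%s)\n", nrow(x$pedigree),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d SNPs, %d phenotype records, rPB,CB = %.2f\n",
              ncol(x$geno), nrow(x$phenotypes), realized_rpbcb(x$gv)))
  invisible(x)
}
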