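test_that("gene dropping conserves Mendelian transmission and CB structure", {
  ds <- tiny_data()
  ped <- ds$pedigree
  H1 <- ds$haplo$paternal
  H2 <- ds$haplo$maternal

  # dose = paternal + maternal allele everywhere
  expect_identical(ds$geno_clean, {
    g <- H1 + H2; storage.mode(g) <- "integer"
    colnames(g) <- colnames(ds$geno_clean); g
  })

  # every CB animal has a terminal-line sire and an F1 sow dam
  cb <- ped[ped$line == "CB", ]
  expect_gt(nrow(cb), 0)
  expect_true(all(ped$line[match(cb$sire, ped$id)] == "terminal"))
  expect_true(all(ped$line[match(cb$dam, ped$id)] == "F1sow"))

  # transmission oracle: each transmitted haplotype is one of the parent's
  # two alleles, locus by locus, for every non-founder
  kids <- ped[!is.na(ped$sire), ]
  ok_pat <- vapply(kids$id, function(id) {
    s <- kids$sire[kids$id == id]
    all(H1[id, ] == H1[s, ] | H1[id, ] == H2[s, ])
  }, TRUE)
  ok_mat <- vapply(kids$id, function(id) {
    d <- kids$dam[kids$id == id]
    all(H2[id, ] == H1[d, ] | H2[id, ] == H2[d, ])
  }, TRUE)
  expect_true(all(ok_pat))
  expect_true(all(ok_mat))

  # generation strictly increases child over known parents
  gen <- setNames(ped$generation, ped$id)
  expect_true(all(gen[kids$id] > pmax(gen[kids$sire], gen[kids$dam])))
})

test_that("founder allele frequencies respect maf_range and heterozygosity", {
  ds <- tiny_data()
  ped <- ds$pedigree
  founders <- ped$id[ped$generation == 0]
  g <- ds$geno_clean[founders, ]
  n <- length(founders)
  freq <- colMeans(g) / 2
  # binomial sampling tolerance at 2n gametes (4 SDs)
  tolb <- 4 * sqrt(0.25 / (2 * n))
  expect_true(all(freq >= 0.05 - tolb & freq <= 0.5 + tolb))

  # founder heterozygosity matches 2p(1-p) within sampling error
  het <- colMeans(g == 1)
  expected <- 2 * freq * (1 - freq)
  expect_lt(mean(abs(het - expected)), 0.03)
})

test_that("zero CB tier yields a purely purebred pedigree", {
  cfg <- tiny_config(n_cb_sires = 0)
  pop <- simulate_population(cfg)
  expect_false(any(pop$pedigree$line %in% c("CB", "F1sow")))
  expect_setequal(unique(pop$pedigree$line),
                  c("terminal", "maternal1", "maternal2"))
})

test_that("same seed gives identical datasets; config validation works", {
  a <- suppressWarnings(suppressMessages(simulate_dataset(tiny_config())))
  b <- tiny_data()
  expect_identical(a$geno, b$geno)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$phenotypes, b$phenotypes)

  expect_error(sim_config(n_founders_per_line = 0), "positive")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(h2_target = c(rfi = 1.2, adg = 0.3)), "h2_target")
  expect_error(sim_config(n_cb_sires = 5, n_f1_sows = 0), "impossible mating")
})

test_that("genetic values: identical contexts give rPB,CB = 1, line-context lowers it", {
  ds <- tiny_data()  # dominance 0.2, line_context_sd 0
  expect_equal(realized_rpbcb(ds$gv), 1)

  # single locus, a = 1, d = 0: additive variance ~ 2p(1-p)
  p <- 0.3; n <- 5000
  set.seed(9)
  x <- matrix(rbinom(n, 2, p), n, 1,
              dimnames = list(paste0("i", 1:n), "snp00001"))
  qtl <- structure(list(qtl_ids = "snp00001",
                        additive = matrix(1, 1, 1, dimnames = list("snp00001", "t")),
                        dominance = matrix(0, 1, 1),
                        line_dev = matrix(0, 1, 1),
                        traits = "t"), class = "qtl_model")
  ped <- data.frame(id = rownames(x), sire = NA, dam = NA)
  gv <- genetic_values(ped, x, qtl)
  expect_equal(var(gv$pb[, 1]), 2 * p * (1 - p), tolerance = 0.05)

  # calibrated line-context SD hits the target correlation across seeds
  # (default-size config: the tiny fixture's 60 QTL are too few for the
  # emergent correlation to stabilize)
  cfg <- calibrate_line_context(sim_config(seed = 42), target_r = 0.66)
  r <- vapply(1:3, function(s) {
    c2 <- cfg; c2$seed <- 100L + s
    pop <- simulate_population(c2)
    realized_rpbcb(genetic_values(pop$pedigree, pop$geno, pop$qtl))
  }, 0)
  expect_true(all(abs(r - 0.66) < 0.1))
})

test_that("phenotypes carry the planted structure", {
  # no-noise config: heritability 1 and no environmental effects make the
  # phenotype an affine function of the genetic value
  cfg0 <- tiny_config(h2_target = c(rfi = 1, adg = 1),
                      env = list(farm_batch_sd = 0, sex_shift = 0,
                                 age_slope = 0, duration_slope = 0))
  pop <- simulate_population(cfg0)
  gv <- genetic_values(pop$pedigree, pop$geno, pop$qtl)
  phe <- simulate_phenotypes(pop$pedigree, gv, cfg0)
  pb <- phe[phe$line == "terminal", ]
  expect_equal(cor(pb$adg, gv$pb[pb$id, "adg"]), 1, tolerance = 1e-12)

  # planted DFI coefficients recovered by OLS (environment off, so the ADG
  # regressor is not confounded with its own covariate terms)
  truth <- attr(phe, "truth")
  fit <- lm(phe$dfi ~ phe$adg + phe$backfat +
              metabolic_weight(phe$w_start, phe$w_end))
  cf <- coef(fit)[2:4]
  se <- summary(fit)$coefficients[2:4, 2]
  planted <- truth$dfi_coef[c("adg", "backfat", "mw")]
  expect_true(all(abs(cf - planted) < 3 * se + 1e-8))

  # farm x batch shifts match group-mean contrasts of the raw trait
  cfg1 <- tiny_config(h2_target = c(rfi = 0.3, adg = 0.3),
                      env = list(farm_batch_sd = 80, age_slope = 0,
                                 duration_slope = 0, sex_shift = 0))
  pop1 <- simulate_population(cfg1)
  gv1 <- genetic_values(pop1$pedigree, pop1$geno, pop1$qtl)
  phe1 <- simulate_phenotypes(pop1$pedigree, gv1, cfg1)
  tr1 <- attr(phe1, "truth")
  pb1 <- phe1[phe1$line == "terminal", ]
  fb <- interaction(pb1$farm, pb1$batch, drop = TRUE)
  gm <- tapply(pb1$adg, fb, mean)
  shift <- tr1$fb_shift_adg[names(gm)]
  # centered group means track centered planted shifts
  expect_gt(cor(gm - mean(gm), shift - mean(shift)), 0.9)

  # realized heritability of the ADG genetic component is near target
  ds <- tiny_data()
  t2 <- attr(ds$phenotypes, "truth")
  h2 <- var(t2$g_adg) / (var(t2$g_adg) + (1 - 0.30) / 0.30 * var(t2$g_adg))
  expect_equal(h2, 0.30, tolerance = 1e-6)
})

test_that("corrupt_genotypes plants what it logs and nothing else", {
  ds <- tiny_data()
  g <- ds$geno_clean
  ped <- ds$pedigree

  # zero rates: identity
  out0 <- corrupt_genotypes(g, ped, 0, 0, seed = 1)
  expect_identical(out0$geno, g)
  expect_identical(out0$log$n_missing, 0L)

  # missingness rate recovered within binomial error
  out1 <- corrupt_genotypes(g, ped, missing_rate = 0.05, seed = 2)
  frac <- mean(is.na(out1$geno))
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / length(g)))

  # every planted Mendelian defect is visible to the detector
  out2 <- corrupt_genotypes(g, ped, missing_rate = 0.02,
                            mendel_error_rate = 0.01, seed = 3)
  log <- out2$log$mendel
  expect_gt(nrow(log), 0)
  for (i in seq_len(min(nrow(log), 50))) {
    pd <- out2$geno[log$parent[i], log$snp[i]]
    od <- out2$geno[log$id[i], log$snp[i]]
    expect_false(is.na(pd) || is.na(od))
    expect_true((pd == 0 && od == 2) || (pd == 2 && od == 0))
  }
})
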