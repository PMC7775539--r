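test_that("SNP QC applies the call-rate and strict MAF rules", {
  g <- rand_geno(40, 6, p = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3), seed = 2)
  g[1:6, 1] <- NA                         # 15% missing -> dropped
  g[, 2] <- 0L                            # monomorphic -> dropped
  g[, 3] <- c(rep(1L, 4), rep(0L, 36))    # maf = 4/80 = 0.05 -> retained
  g[, 4] <- c(rep(1L, 3), rep(0L, 37))    # maf < 0.05 -> dropped
  res <- snp_qc(g)
  expect_setequal(res$report$dropped, colnames(g)[c(1, 2, 4)])
  expect_true("snp0003" %in% colnames(res$geno))
  expect_identical(res$report$n_dropped + res$report$n_retained, ncol(g))
})

test_that("sample QC after SNP QC matches a hand-computed toy", {
  # crafted 5 x 4 matrix: SNP2 has 40% missing (dropped first); afterwards
  # sample e misses 2/3 of remaining SNPs and is dropped
  g <- matrix(c(0L, 1L, 2L, 1L, 0L,
                NA, NA, 1L, 1L, 1L,
                1L, 1L, 0L, 2L, NA,
                2L, 0L, 1L, 0L, NA),
              5, 4, dimnames = list(letters[1:5], paste0("m", 1:4)))
  s1 <- snp_qc(g, call_rate_min = 0.8, maf_min = 0.05)
  expect_identical(s1$report$dropped, "m2")
  s2 <- sample_qc(s1$geno, call_rate_min = 0.8)
  expect_identical(s2$report$dropped, "e")
  expect_setequal(rownames(s2$geno), c("a", "b", "c", "d"))

  # fully typed sample retained
  expect_true("a" %in% rownames(s2$geno))
})

test_that("Mendelian check flags opposite homozygotes beyond tolerance", {
  ped <- data.frame(id = c("p", "o1", "o2"), sire = c(NA, "p", "p"),
                    dam = NA)
  g <- rand_geno(3, 200, seed = 3)
  rownames(g) <- c("p", "o1", "o2")
  # make o1 consistent with p everywhere
  gp <- g["p", ]
  g["o1", gp == 0] <- sample(c(0L, 1L), sum(gp == 0), TRUE)
  g["o1", gp == 2] <- sample(c(1L, 2L), sum(gp == 2), TRUE)
  g["o2", ] <- g["o1", ]
  # plant 5% opposite-homozygote defects in o2
  hom <- which(gp != 1)
  bad <- hom[seq_len(ceiling(0.05 * ncol(g)))]
  g["o2", bad] <- 2L - gp[bad]

  mc <- mendel_check(g, ped, tol = 0.01)
  expect_identical(mc$flagged[mc$offspring == "o1"], FALSE)
  expect_identical(mc$flagged[mc$offspring == "o2"], TRUE)

  # heterozygous parent never inconsistent
  g2 <- g
  g2["p", ] <- 1L
  mc2 <- mendel_check(g2, ped, tol = 0)
  expect_true(all(mc2$n_inconsistent == 0))

  # planted defects from the simulator are all counted by the detector, and
  # every pair whose planted rate exceeds the tolerance is flagged
  ds <- tiny_data()
  out <- corrupt_genotypes(ds$geno_clean, ds$pedigree,
                           mendel_error_rate = 0.05, seed = 8)
  mc3 <- mendel_check(out$geno, ds$pedigree, tol = 0.01)
  planted <- table(paste(out$log$mendel$parent, out$log$mendel$id))
  key <- paste(mc3$parent, mc3$offspring)
  hit <- match(names(planted), key)
  expect_false(anyNA(hit))
  expect_true(all(mc3$n_inconsistent[hit] >= as.integer(planted)))
  over_tol <- as.integer(planted) / mc3$n_checked[hit] > 0.01
  expect_true(all(mc3$flagged[hit][over_tol]))
})

test_that("near-zero-variance filter uses the 95/5 count-ratio rule", {
  g <- cbind(c(rep(0L, 96), rep(1L, 4)),            # ratio 24 -> dropped
             c(rep(0L, 50), rep(1L, 30), rep(2L, 20)),  # 5/3 -> kept
             rep(1L, 100),                          # constant -> dropped
             c(rep(0L, 95), rep(1L, 5)))            # ratio 19 -> kept
  dimnames(g) <- list(sprintf("i%03d", 1:100), paste0("v", 1:4))
  res <- near_zero_variance_filter(g)
  expect_setequal(res$report$dropped, c("v1", "v3"))
  expect_setequal(colnames(res$geno), c("v2", "v4"))
})

test_that("correlation pruning matches the greedy rule and its postcondition", {
  # two perfectly correlated SNPs: exactly one goes
  set.seed(5)
  a <- rbinom(60, 2, 0.4)
  g <- cbind(a, a, rbinom(60, 2, 0.4))
  dimnames(g) <- list(sprintf("i%02d", 1:60), c("s1", "s2", "s3"))
  storage.mode(g) <- "integer"
  res <- correlation_prune(g, 0.8)
  expect_identical(res$report$n_dropped, 1L)
  expect_true("s3" %in% colnames(res$geno))

  # three pairwise-correlated SNPs: exactly two go, matching a brute-force
  # run of the stated greedy rule
  greedy_oracle <- function(X, cutoff) {
    cm <- abs(cor(X)); diag(cm) <- 0
    alive <- rep(TRUE, ncol(X))
    repeat {
      sub <- cm[alive, alive, drop = FALSE]
      if (max(sub) <= cutoff) break
      ia <- which(alive)
      w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      pair <- ia[sort(w)]
      ma <- rowMeans(cm[pair, alive, drop = FALSE])
      alive[if (ma[1] >= ma[2]) pair[1] else pair[2]] <- FALSE
    }
    colnames(X)[alive]
  }
  set.seed(6)
  base <- rnorm(100)
  X <- sapply(1:3, function(i) base + rnorm(100, 0, 0.3))
  X <- cbind(X, rnorm(100))
  g2 <- matrix(as.integer(cut(X, breaks = quantile(X, 0:3 / 3),
                              include.lowest = TRUE)) - 1L, 100)
  dimnames(g2) <- list(sprintf("i%03d", 1:100), paste0("q", 1:4))
  keep_pkg <- colnames(correlation_prune(g2, 0.5)$geno)
  expect_identical(keep_pkg, greedy_oracle(impute_mean(g2), 0.5))

  # postcondition on real simulated LD
  ds <- tiny_data()
  founders <- ds$pedigree$id[ds$pedigree$generation == 0]
  gf <- ds$geno_clean[founders, ]
  gf <- near_zero_variance_filter(gf)$geno
  pruned <- correlation_prune(gf, 0.8)
  cc <- abs(cor(impute_mean(pruned$geno)))
  diag(cc) <- 0
  expect_lte(max(cc), 0.8 + 1e-12)
  # LD blocks give the pruner real work
  expect_gt(pruned$report$n_dropped, 0.2 * ncol(gf))
})

test_that("panel harmonization restricts and reorders; empty set errors", {
  g <- rand_geno(10, 8, seed = 7)
  panel <- c("snp0005", "snp0002", "snp0007")
  out <- harmonize_panels(g, panel)
  expect_identical(colnames(out), panel)
  # permuted input columns still give PB panel order
  out2 <- harmonize_panels(g[, sample(ncol(g))], panel)
  expect_identical(out2, out)
  expect_identical(harmonize_panels(g, colnames(g)), g)
  expect_error(harmonize_panels(g, character(0)), "empty")
  expect_error(harmonize_panels(g, c("snp0002", "nope")), "absent")
})

test_that("QC cascade report counts reconcile per rule", {
  ds <- tiny_data()
  qc <- suppressMessages(qc_pipeline(ds$geno, ds$pedigree,
                                     subsets = list(pb = ds$pedigree$id[
                                       ds$pedigree$line == "terminal"])))
  r <- qc$reports
  expect_identical(r$snp$n_dropped + r$snp$n_retained, ncol(ds$geno))
  expect_identical(r$sample$n_dropped + r$sample$n_retained, nrow(ds$geno))
  expect_identical(r$mendel$n_dropped + r$mendel$n_retained,
                   r$sample$n_retained)
  expect_identical(r$nzv_pb$n_dropped + r$nzv_pb$n_retained,
                   r$snp$n_retained)
  expect_identical(length(qc$panels$pb), r$prune_pb$n_retained)
  # panel SNPs all survive the global stages
  expect_true(all(qc$panels$pb %in% colnames(qc$geno)))
})
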