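test_that("Spearman accuracy and summaries match naive oracles", {
  expect_equal(as.numeric(spearman_sc(1:10, (1:10)^3)), 1)
  expect_equal(as.numeric(spearman_sc(1:10, 10:1)), -1)
  # ties handled by average ranks: compare against Pearson-on-ranks oracle
  set.seed(14)
  a <- sample(rep(1:5, 4)); b <- a + rnorm(20)
  expect_equal(as.numeric(spearman_sc(a, b)), naive_spearman(a, b))
  d <- spearman_sc(1:5, rep(2, 5))
  expect_identical(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
  expect_error(spearman_sc(1:2, 1:2), ">= 3")

  expect_equal(summarize_sc(c(0.1, 0.2, 0.3)),
               c(median = 0.2, iqr = 0.1))
  expect_equal(summarize_sc(0.4), c(median = 0.4, iqr = 0))
  set.seed(15)
  v <- rnorm(25)
  s <- summarize_sc(v)
  sv <- sort(v)
  expect_equal(unname(s["median"]), sv[13])
  expect_equal(unname(s["iqr"]),
               unname(quantile(v, 0.75) - quantile(v, 0.25)))
})

test_that("bootstrap accuracy is deterministic and consistent", {
  bs <- bootstrap_sc(1:20, (1:20)^2, B = 50, seed = 3)
  expect_equal(bs$median, 1)
  expect_equal(bs$iqr, 0)
  bs2 <- bootstrap_sc(1:20, (1:20)^2, B = 50, seed = 3)
  expect_identical(bs$values, bs2$values)

  set.seed(16)
  obs <- rnorm(200)
  pred <- obs + rnorm(200, 0, 0.8)
  point <- as.numeric(spearman_sc(obs, pred))
  bs3 <- bootstrap_sc(obs, pred, B = 500, seed = 4)
  expect_lt(abs(bs3$median - point), 0.05)
})

test_that("SNP ranking matches a brute-force rank-correlation oracle", {
  set.seed(17)
  X <- matrix(rbinom(50 * 20, 2, 0.4), 50,
              dimnames = list(NULL, sprintf("m%02d", 1:20)))
  y <- 2 * X[, 7] + rnorm(50, 0, 0.5)
  storage.mode(X) <- "double"
  rk <- rank_snps_spearman(X, y)
  # brute-force oracle
  rho <- apply(X, 2, function(col) naive_spearman(col, y))
  ord <- order(-abs(rho), seq_along(rho))
  expect_identical(as.character(rk), colnames(X)[ord])
  expect_equal(unname(attr(rk, "rho")), unname(rho[ord]))
  expect_identical(rk[1], "m07")

  # monotone perfect association ranks first with |rho| = 1
  y2 <- as.numeric(X[, 3])
  rk2 <- rank_snps_spearman(X + 0, y2)
  expect_identical(rk2[1], "m03")
  expect_equal(abs(attr(rk2, "rho")[1]), 1)

  # permuting samples leaves the ranking unchanged
  perm <- sample(50)
  expect_identical(as.character(rank_snps_spearman(X[perm, ], y[perm])),
                   as.character(rk))

  # constant column ranks last with rho 0
  X2 <- cbind(X, const = 1)
  expect_message(rk3 <- rank_snps_spearman(X2, y), "constant")
  expect_identical(rk3[21], "const")

  # top-k prefixes are nested
  expect_identical(select_top_k(rk, 5), rk[1:5])
  expect_identical(select_top_k(rk, 20), as.character(rk))
  expect_true(all(select_top_k(rk, 5) %in% select_top_k(rk, 10)))
  expect_error(select_top_k(rk, 21), "exceeds")
})

test_that("CV plans partition ids, respect families, and are reproducible", {
  ids <- sprintf("i%03d", 1:100)
  pl <- build_cv_plan(ids, k = 10, seed = 5)
  folds <- pl$folds[[1]]
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), sort(ids))
  expect_true(all(vapply(tests, length, 0L) == 10))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_identical(build_cv_plan(ids, k = 10, seed = 5), pl)
  expect_false(identical(build_cv_plan(ids, k = 10, seed = 6), pl))

  # family blocking: no train animal shares a family with a test animal
  fam <- rep(sprintf("s%02d", 1:20), each = 5)
  plf <- build_cv_plan(ids, k = 5, repeats = 2, seed = 7, families = fam)
  for (r in 1:2) for (f in plf$folds[[r]]) {
    expect_length(intersect(fam[match(f$train, ids)],
                            fam[match(f$test, ids)]), 0)
  }
  expect_error(build_cv_plan(ids[1:10], k = 5, families = rep("f1", 10)),
               "fewer families")
})

test_that("generation assignment and generational splits follow the rules", {
  ped <- data.frame(id = c("a", "b", "c", "d", "e"),
                    sire = c(NA, "a", "b", NA, "c"),
                    dam = c(NA, NA, "d", NA, NA))
  gen <- assign_generations(ped)
  expect_equal(unname(gen[c("a", "b", "c", "d", "e")]), c(0, 1, 2, 0, 3))
  # one known parent at generation 3 -> 4
  ped2 <- rbind(ped, data.frame(id = "f", sire = "e", dam = NA))
  expect_equal(unname(assign_generations(ped2)["f"]), 4)
  cyc <- data.frame(id = c("x", "y"), sire = c("y", "x"), dam = NA)
  expect_error(assign_generations(cyc), "cycle")

  sp <- split_generational(ped2, ped2$id, n_young = 2)
  expect_setequal(sp$test, c("e", "f"))
  expect_setequal(sp$train, c("a", "b", "c", "d"))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(split_generational(ped2, ped2$id, n_young = 0), ">= 1")
  expect_error(split_generational(ped2, c("a", "d"), n_young = 2),
               "distinct generations")
})

test_that("IN/OUT sire partitioning is an exact set split", {
  po <- partition_in_out(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(po$in_sires, c("b", "c"))
  expect_identical(po$out_sires, "d")
  expect_length(partition_in_out(character(0), c("x", "y"))$in_sires, 0)
  all_in <- partition_in_out(letters, c("a", "b"))
  expect_setequal(all_in$in_sires, c("a", "b"))
  expect_length(all_in$out_sires, 0)
  expect_equal(length(po$in_sires) + length(po$out_sires), 3)
})

test_that("scenario specs validate combinations and defaults", {
  sp <- scenario_spec("trn1", "tst1")
  expect_equal(c(sp$k, sp$repeats), c(10, 1))
  sp2 <- scenario_spec("trn3", "tst2")
  expect_equal(c(sp2$k, sp2$repeats), c(5, 5))
  expect_equal(sp2$subset_sizes, c(50, 250, 500, 750, 1000, 1500, 2000))
  expect_equal(sp2$C_grid, c(0.001, 0.1, 1, 5, 10))
  expect_equal(sp2$gamma_grid, c(0.005, 0.05, 0.5, 5))
  expect_error(scenario_spec("trn2", "tst1"), "invalid scenario")
  expect_error(scenario_spec("trn3", "tst1"), "invalid scenario")
})

test_that("run_scenario honours the design contracts on the tiny fixture", {
  bnd <- tiny_bundles()$bundles$rfi
  sp <- scenario_spec("trn3", "tst2", learner = "gblup", k = 4, repeats = 2)
  res <- suppressMessages(run_scenario(sp, bnd, seed = 11))
  # sire-family exclusion: test sires never have progeny in the fold's
  # training CB records
  plan <- attr(res, "plan")
  ped <- bnd$pedigree
  for (r in seq_len(sp$repeats)) for (f in plan$folds[[r]]) {
    train_sires <- unique(ped$sire[match(f$train, ped$id)])
    test_sires <- unique(ped$sire[match(f$test, ped$id)])
    expect_length(intersect(train_sires, test_sires), 0)
  }
  # determinism
  res2 <- suppressMessages(run_scenario(sp, bnd, seed = 11))
  expect_identical(res, res2)

  # trn1-tst2 reports IN and OUT groups covering every sire each fold
  sp3 <- scenario_spec("trn1", "tst2", learner = "svr", subset_sizes = 50,
                       k = 3, C_grid = c(1), gamma_grid = c(0.05))
  res3 <- suppressMessages(run_scenario(sp3, bnd, seed = 12))
  per_fold <- table(res3$fold)
  expect_true(all(per_fold == length(unique(res3$id))))
  expect_setequal(unique(res3$group), c("IN", "OUT"))
  # IN sires really are in that fold's PB training ids
  plan3 <- attr(res3, "plan")
  for (f in seq_len(3)) {
    sub <- res3[res3$fold == f, ]
    expect_true(all(sub$id[sub$group == "IN"] %in%
                      plan3$folds[[1]][[f]]$train))
    expect_false(any(sub$id[sub$group == "OUT"] %in%
                       plan3$folds[[1]][[f]]$train))
  }

  # generational split: single realization, young sires only
  sp4 <- scenario_spec("trn3", "tst2", learner = "gblup",
                       split = "generational")
  res4 <- suppressMessages(run_scenario(sp4, bnd, seed = 13))
  expect_equal(unique(res4$fold), 1)
  gen <- assign_generations(ped)
  cb_gen <- gen[bnd$cb_pheno$id]
  young <- sort(unique(cb_gen), decreasing = TRUE)[1:2]
  young_sires <- unique(ped$sire[match(names(cb_gen)[cb_gen %in% young],
                                       ped$id)])
  expect_true(all(res4$id %in% young_sires))

  summ <- summarize_results(res4)
  expect_true(all(abs(summ$median_sc) <= 1))
  expect_true(all(summ$iqr_sc >= 0))
})
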