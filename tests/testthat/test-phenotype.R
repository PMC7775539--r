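test_that("metabolic weight follows the mid-test 0.75-power formula", {
  expect_equal(metabolic_weight(2, 2), 2^0.75)
  expect_equal(metabolic_weight(0, 0), 0)
  # median PB start/end test weights
  expect_equal(metabolic_weight(31, 130), 80.5^0.75)
  expect_equal(metabolic_weight(c(2, 31), c(2, 130)), c(2^0.75, 80.5^0.75))
  expect_error(metabolic_weight(-1, 5), "non-negative")
})

test_that("test-window filter keeps inclusive bounds", {
  rec <- data.frame(id = letters[1:6],
                    age_start = c(49, 50, 105, 106, 70, 70),
                    duration = c(90, 60, 120, 90, 59, 121))
  kept <- filter_test_window(rec)
  expect_identical(kept$id, c("b", "c"))
  expect_identical(nrow(filter_test_window(rec[0, ])), 0L)
})

test_that("Mahalanobis outlier flagging matches an explicit computation", {
  set.seed(11)
  n <- 80
  x <- matrix(rnorm(n * 4), n)
  # plant one point at squared distance 25 along the first axis
  x[1, ] <- c(5, 0, 0, 0)
  rec <- data.frame(adg = x[, 1], dfi = x[, 2], backfat = x[, 3], mw = x[, 4],
                    farm = "f1", batch = "b1")
  flag <- flag_outliers_mahalanobis(rec, group_cols = c("farm", "batch"))
  d2 <- mahalanobis(x, colMeans(x), cov(x))
  expect_identical(flag, unname(d2 > 12))
  expect_true(flag[1])

  # infinite threshold flags nothing
  expect_false(any(flag_outliers_mahalanobis(rec, c("farm", "batch"),
                                             threshold = Inf)))

  # location invariance: a shifted copy of the group gives the same mask
  rec2 <- rec
  rec2[, 1:4] <- rec2[, 1:4] + 100
  rec2$farm <- "f2"
  both <- rbind(rec, rec2)
  flag2 <- flag_outliers_mahalanobis(both, c("farm", "batch"))
  expect_identical(flag2[1:n], flag2[(n + 1):(2 * n)])

  # small groups are skipped with a warning
  small <- rec[1:4, ]
  expect_warning(fl <- flag_outliers_mahalanobis(small, c("farm", "batch")),
                 "skipped")
  expect_false(any(fl))
})

test_that("RFI is the OLS residual of DFI on ADG, backfat, MW", {
  set.seed(21)
  n <- 1000
  rec <- data.frame(id = sprintf("i%04d", 1:n),
                    adg = rnorm(n, 1000, 100),
                    backfat = rnorm(n, 12, 2),
                    mw = rnorm(n, 27, 2))
  eps <- rnorm(n, 0, 150)
  rec$dfi <- 2 * rec$adg + eps
  rfi <- derive_rfi(rec)
  # orthogonality of OLS residuals
  expect_lt(abs(mean(rfi$rfi)), 1e-10)
  for (v in c("adg", "backfat", "mw"))
    expect_lt(abs(cor(rfi$rfi, rec[[v]])), 1e-10)
  # recovery of the planted feed-intake noise
  expect_gt(cor(rfi$rfi, eps), 0.99)

  expect_error(derive_rfi(rec[1:3, ]), "more than 4")
  bad <- rec
  bad$mw <- bad$adg * 2   # collinear
  expect_error(derive_rfi(bad), "rank deficient")
})

test_that("pre-adjustment drops small farm x batch levels and removes planted shifts", {
  set.seed(31)
  n <- 120
  rec <- data.frame(id = sprintf("i%03d", 1:n),
                    age_start = round(runif(n, 55, 100)),
                    duration = round(runif(n, 70, 110)),
                    farm = "f1",
                    batch = rep(c("b1", "b2", "b3"), c(60, 51, 9)),
                    sex = "M")
  shifts <- c(b1 = 0, b2 = 120, b3 = -50)
  rec$adg <- 1000 + shifts[rec$batch] + rnorm(n, 0, 10)

  adj <- preadjust_trait(rec, "adg")
  # the 9-record level is gone
  expect_identical(attr(adj, "dropped_levels"), "f1.b3")
  expect_false(any(rec$id[rec$batch == "b3"] %in% adj$id))
  # planted shifts are removed: group means agree after adjustment
  g <- tapply(adj$value, rec$batch[match(adj$id, rec$id)], mean)
  expect_lt(abs(g["b1"] - g["b2"]), 3 * 10 / sqrt(30))

  # null model: adjusted values equal originals up to the fitted noise
  rec0 <- rec[rec$batch == "b1", ]
  adj0 <- preadjust_trait(rec0, "adg")
  expect_gt(cor(adj0$value, rec0$adg[match(adj0$id, rec0$id)]), 0.9)

  # idempotence: re-adjusting changes nothing
  rec1 <- rec[rec$batch != "b3", ]
  a1 <- preadjust_trait(rec1, "adg")
  rec2 <- rec1
  rec2$adg <- a1$value[match(rec2$id, a1$id)]
  a2 <- preadjust_trait(rec2, "adg")
  expect_lt(max(abs(a2$value - a1$value)), 1e-8)

  expect_error(preadjust_trait(rec[rec$batch == "b3", ], "adg"),
               "fewer than 10")
})

test_that("sire averaging covers retained offspring only", {
  ped <- data.frame(id = c("c1", "c2", "c3", "c4", "s1", "s2"),
                    sire = c("s1", "s1", "s1", NA, NA, NA),
                    dam = NA)
  adj <- data.frame(id = c("c1", "c2", "c3"), value = c(1, 2, 3))
  sa <- sire_average(adj, ped)
  expect_identical(sa$sire_id, "s1")
  expect_equal(sa$mean, 2)
  expect_identical(sa$n, 3L)

  # unknown sire: excluded with a message; childless sire absent
  adj2 <- rbind(adj, data.frame(id = "c4", value = 10))
  expect_message(sa2 <- sire_average(adj2, ped), "unknown sire")
  expect_identical(sa2$sire_id, "s1")
})

test_that("full phenotype pipeline runs in order on the simulated subsets", {
  ds <- tiny_data()
  phe <- ds$phenotypes
  pb <- suppressWarnings(prep_phenotypes(phe[phe$line == "terminal", ],
                                         ds$pedigree, "pb"))
  # monotone record counts through the pipeline stages
  expect_true(all(diff(pb$report) <= 0))
  # only surviving ids appear, and none outside the window
  raw <- phe[phe$line == "terminal", ]
  bad_window <- raw$id[raw$age_start < 50 | raw$age_start > 105 |
                         raw$duration < 60 | raw$duration > 120]
  expect_length(intersect(pb$adjusted$id, bad_window), 0)

  cbs <- suppressWarnings(prep_phenotypes(phe[phe$line == "CB", ],
                                          ds$pedigree, "cb_sire"))
  expect_false(is.null(cbs$sire_means))
  # offspring_per_sire = 8 in the fixture; attrition only lowers counts
  expect_lte(max(cbs$sire_means$n), 8)
  expect_equal(median(cbs$sire_means$n), 8, tolerance = 0.25)
  # sire means recompute from the adjusted table
  one <- cbs$sire_means$sire_id[1]
  kids <- ds$pedigree$id[!is.na(ds$pedigree$sire) & ds$pedigree$sire == one]
  expect_equal(cbs$sire_means$rfi[1],
               mean(cbs$adjusted$rfi[cbs$adjusted$id %in% kids]))
})
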