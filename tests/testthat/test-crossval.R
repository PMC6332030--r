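test_that("shifted k-fold split takes every k-th item and partitions exactly once", {
  expect_equal(kfoldSplit(0:9, k = 10, run = 0)$test, 0)
  expect_equal(kfoldSplit(0:9, k = 5, run = 1)$test, c(1, 6))
  for (n in c(7, 10, 23)) for (k in c(2, 3, 5, 7)) {
    if (k > n) next
    ids <- seq_len(n)
    tests <- lapply(0:(k - 1), function(r) kfoldSplit(ids, k, r)$test)
    expect_equal(sort(unlist(tests)), ids, info = paste(n, k))
    expect_equal(sum(lengths(tests)), n)
    for (r in 0:(k - 1))
      expect_equal(sort(c(tests[[r + 1]], kfoldSplit(ids, k, r)$train)), ids)
  }
  expect_error(kfoldSplit(1:3, k = 5, run = 0), "exceeds")
})

test_that("noiseless cross-validation reaches Q2 = 1", {
  ss <- generateSyntheticSet(60, 8, sigma = 0, seed = 5, constant = 0.3)
  cfg <- gaDefaultConfig(); cfg$fit$constant <- TRUE
  rep <- GroupAdditivity:::.crossValidateProfiles(ss@profiles, ss@values,
                                                  k = 10, config = cfg)
  expect_equal(rep@N, 60L)
  expect_gt(rep@Q2, 1 - 1e-9)
})

test_that("noisy cross-validation: Q2 < 1 and SD_cv tracks the noise level", {
  cfg <- gaDefaultConfig(); cfg$fit$constant <- TRUE
  sds <- vapply(1:5, function(s) {
    ss <- generateSyntheticSet(200, 6, sigma = 0.5, seed = s)
    rep <- GroupAdditivity:::.crossValidateProfiles(ss@profiles, ss@values,
                                                    k = 10, config = cfg)
    expect_lt(rep@Q2, 1)
    rep@SD
  }, numeric(1))
  expect_gt(mean(sds), 0.4)
  expect_lt(mean(sds), 0.65)
})

test_that("cross-validated SD is no smaller than the training-fit SD", {
  cfg <- gaDefaultConfig(); cfg$fit$constant <- TRUE
  diffs <- vapply(1:5, function(s) {
    ss <- generateSyntheticSet(120, 6, sigma = 0.4, seed = 100 + s)
    tab <- GroupAdditivity:::.fitProfiles(ss@profiles, ss@values, config = cfg)
    rep <- GroupAdditivity:::.crossValidateProfiles(ss@profiles, ss@values,
                                                    k = 10, config = cfg)
    rep@SD - fitStats(tab)$SD
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("test molecules losing three-molecule support are excluded", {
  # RARE occurs in molecules 1..3 only; whenever one of them is held out,
  # the reduced training set leaves RARE with 2 exemplars, so that test
  # molecule is excluded from the pooling
  profiles <- c(
    lapply(1:3, function(i)
      new("FragmentProfile", groupCounts = c(A = 1, RARE = 1),
          specialCounts = setNames(numeric(), character()),
          name = paste0("rare", i))),
    lapply(4:12, function(i)
      new("FragmentProfile", groupCounts = c(A = i),
          specialCounts = setNames(numeric(), character()),
          name = paste0("plain", i))))
  values <- c(4, 4, 4, (4:12) * 1.5)
  cfg <- gaDefaultConfig(); cfg$fit$constant <- FALSE
  rep <- GroupAdditivity:::.crossValidateProfiles(profiles, values, k = 3,
                                                  config = cfg)
  expect_equal(rep@N, 9L)
  expect_false(any(grepl("^rare", rep@predictions$id)))
  expect_equal(sum(rep@runs$evaluable), 9L)
  expect_equal(sum(rep@runs$test), 12L)
})

test_that("the scheme is deterministic given the input ordering", {
  ss <- generateSyntheticSet(45, 5, sigma = 0.2, seed = 9)
  cfg <- gaDefaultConfig(); cfg$fit$constant <- TRUE
  r1 <- GroupAdditivity:::.crossValidateProfiles(ss@profiles, ss@values,
                                                 k = 9, config = cfg)
  r2 <- GroupAdditivity:::.crossValidateProfiles(ss@profiles, ss@values,
                                                 k = 9, config = cfg)
  expect_identical(r1@predictions, r2@predictions)
  expect_identical(r1@Q2, r2@Q2)
})

test_that("CVReport serializes with the table-footer fields", {
  ss <- generateSyntheticSet(30, 4, sigma = 0.1, seed = 3)
  cfg <- gaDefaultConfig(); cfg$fit$constant <- TRUE
  rep <- GroupAdditivity:::.crossValidateProfiles(ss@profiles, ss@values,
                                                  k = 10, config = cfg)
  js <- jsonlite::fromJSON(cvReportJSON(rep))
  expect_equal(js$k, 10)
  expect_named(js, c("k", "Q2", "MAE_cv", "SD_cv", "N_cv", "runs",
                     "predictions"), ignore.order = TRUE)
  expect_equal(js$N_cv, rep@N)
})
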