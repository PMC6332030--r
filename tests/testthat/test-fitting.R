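prof <- function(name, counts, specials = NULL) {
  new("FragmentProfile", groupCounts = counts,
      specialCounts = if (is.null(specials))
        setNames(numeric(), character()) else specials,
      name = name)
}

test_that("design matrix receives occurrence counts, constant and drops", {
  p1 <- prof("m1", c(`C sp3|H3C` = 2))
  p2 <- prof("m2", c(`C sp3|H3C` = 1))
  dm <- buildDesignMatrix(list(p1, p2), c(1, 2))
  expect_equal(dim(dm$X), c(2L, 2L))
  expect_equal(unname(dm$X[, "C sp3|H3C"]), c(2, 1))
  expect_equal(unname(dm$X[, "Const"]), c(1, 1))

  # special counts enter as counts, not indicators
  p3 <- prof("hc20", c(`C sp3|H3C` = 2, `C sp3|H2C2` = 18),
             specials = c(Alkane = 20))
  dm3 <- buildDesignMatrix(list(p3), 0, constant = FALSE)
  expect_equal(unname(dm3$X[, "Alkane"]), 20)

  # schema columns that are all-zero get dropped with a report
  dm4 <- buildDesignMatrix(list(p1), 1, schema = c("C sp3|H3C", "ghost"),
                           constant = FALSE)
  expect_equal(attr(dm4, "dropped"), "ghost")
  expect_equal(colnames(dm4$X), "C sp3|H3C")

  expect_error(buildDesignMatrix(list(p1, p2), c(1, NA)), "m2")
})

test_that("Gauss-Seidel equals the direct least-squares oracle", {
  # identity design: contributions equal the experimental values
  X <- diag(4); colnames(X) <- paste0("g", 1:4)
  y <- c(2, -1, 0.5, 7)
  expect_equal(unname(gaussSeidelSolve(X, y)), y, tolerance = 1e-7)

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:50, 1); p <- sample(2:min(20, n - 1), 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    gs <- gaussSeidelSolve(X, y)
    direct <- qr.solve(crossprod(X), crossprod(X, y))
    expect_lt(max(abs(gs - direct)), 1e-6)
  }

  # non-convergence carries the last iterate
  Xc <- cbind(a = c(1, 1, 0), b = c(1, 0, 1))  # correlated columns
  err <- tryCatch(gaussSeidelSolve(Xc, c(1, 2, 3), maxIter = 1L),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "did not converge")
  expect_length(err$beta, 2L)
})

test_that("fit statistics match their definitions", {
  expect_equal(fitStatistics(c(1, 2, 3), c(1, 2, 3)),
               list(R2 = 1, MAE = 0, SD = 0, N = 3L))
  fs <- fitStatistics(c(0, 0), c(1, -1))
  expect_equal(fs$MAE, 1)
  set.seed(7)
  y <- rnorm(40); yh <- y + rnorm(40, 0, 0.3)
  fs <- fitStatistics(yh, y)
  r <- y - yh
  expect_equal(fs$R2, 1 - sum(r^2) / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(fs$MAE, mean(abs(r)), tolerance = 1e-12)
  expect_equal(fs$SD, sd(r), tolerance = 1e-12)
  expect_equal(fitStatistics(yh, y, rmse = TRUE)$SD, sqrt(mean(r^2)),
               tolerance = 1e-12)
  expect_warning(fitStatistics(c(1, 2), c(3, 3)), "constant")
})

test_that("fitting profiles recovers generating contributions", {
  ss <- generateSyntheticSet(50, 8, sigma = 0, seed = 11, constant = 0.7)
  cfg <- gaDefaultConfig(); cfg$fit$constant <- TRUE
  tab <- GroupAdditivity:::.fitProfiles(ss@profiles, ss@values, config = cfg)
  e <- tableEntries(tab)
  expect_lt(max(abs(e$contribution - ss@truth[e$key])), 1e-6)
  expect_lt(abs(tableConstant(tab) - 0.7), 1e-6)
  # occurrence / molecule bookkeeping
  expect_true(all(e$occurrences >= e$molecules))
})

test_that("fit statistics are gated on three-molecule confirmation", {
  # groups A (in 6 molecules) and RARE (in 2): molecules containing RARE
  # are excluded from the reported statistics
  profiles <- c(
    lapply(1:6, function(i) prof(paste0("a", i), c(A = i))),
    lapply(1:2, function(i) prof(paste0("r", i), c(A = 1, RARE = 1))))
  values <- c(1:6 * 2, 3.5, 3.5)
  cfg <- gaDefaultConfig(); cfg$fit$constant <- FALSE
  tab <- GroupAdditivity:::.fitProfiles(profiles, values, config = cfg)
  expect_equal(fitStats(tab)$based_on, 8)
  expect_equal(fitStats(tab)$N, 6L)
})

test_that("fitTable runs end-to-end on molecules and extends to new groups", {
  smis <- c("CCO", "CCCO", "CCCCO", "CCC", "CCCC", "CCCCC", "CCO", "CCCO")
  mols <- lapply(seq_along(smis), function(i) {
    m <- mol(smis[i], paste0("m", i))
    m@properties <- c(logS = as.numeric(i))
    m
  })
  cfg <- gaDefaultConfig()
  cfg$fit$specials$logS <- character()  # composition-only toy fit
  tab <- fitTable(mols, "logS", cfg)
  expect_s4_class(tab, "ParameterTable")
  keysBefore <- tableEntries(tab)$key
  expect_true("O|HC" %in% keysBefore)

  # a molecule with a brand-new group extends the table without code change
  extra <- mol("CCBr", "bromide"); extra@properties <- c(logS = 0.5)
  tab2 <- fitTable(c(mols, list(extra)), "logS", cfg)
  expect_true("C sp3|H2CBr" %in% tableEntries(tab2)$key)
  expect_error(fitTable(list(), "logS"), "empty training set")
})
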