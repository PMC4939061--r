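test_that("odds ratio follows ad/bc with a zero-cell refusal", {
  expect_equal(oddsRatio(c(a = 2, b = 1, c = 1, d = 2)), 4)
  expect_equal(oddsRatio(c(a = 9, b = 9, c = 9, d = 9)), 1)
  expect_true(is.na(oddsRatio(c(a = 20, b = 0, c = 0, d = 0))))
})

test_that("null cell covariance handles concordant and discordant families", {
  expect_equal(nullCellCovariance(1L, 1L), matrix(0, 9, 9))
  C <- nullCellCovariance(1L, 9L)   # (mm,mm) vs (MM,MM)
  expected <- matrix(0, 9, 9)
  expected[1, 1] <- expected[9, 9] <- 0.25
  expected[1, 9] <- expected[9, 1] <- -0.25
  expect_equal(C, expected)
})

test_that("closed-form cell covariance equals exhaustive label-swap covariance", {
  for (seed in 1:3) {
    set.seed(seed)
    u <- sample(1:9, 10L, TRUE)
    v <- sample(1:9, 10L, TRUE)
    expect_equal(nullCellCovariance(u, v), enumCellCov(u, v),
                 tolerance = 1e-12)
  }
})

test_that("replicating every family m times scales the variance by 1/m", {
  co <- randomCohort(12L, seed = 3L)
  cfg <- familyCellConfig(co, 1L, 2L)
  tb <- buildGenotypeTables(co, 1L, 2L)
  v1 <- varLogOrCase(tb$affected, cfg$u, cfg$v)
  for (m in c(2L, 4L)) {
    um <- rep(cfg$u, m); vm <- rep(cfg$v, m)
    vm_var <- varLogOrCase(tb$affected * m, um, vm)
    expect_equal(vm_var, v1 / m, tolerance = 1e-12)
  }
})

test_that("identical affected and unaffected tables give G = 0, p = 1", {
  # families 1 and 2 exchange cells (1,1) and (2,1), family 3 is a
  # concordant double het, so the two tables are equal cell-wise while
  # the label-swap variance stays positive
  co <- makeCohort(aff1 = c(1L, 2L, 2L), aff2 = c(1L, 1L, 2L),
                   un1 = c(2L, 1L, 2L), un2 = c(1L, 1L, 2L))
  res <- gdsp(co, "s1", "s2")
  expect_identical(res@status, "OK")
  expect_equal(res@gDsp, 0)
  expect_equal(res@pValue, 1)
})

test_that("p-values are two-sided standard-normal tails of G", {
  co <- randomCohort(60L, seed = 8L)
  res <- gdsp(co, 1L, 2L)
  expect_identical(res@status, "OK")
  expect_equal(res@pValue, 2 * pnorm(-abs(res@gDsp)))
  expect_gt(res@varLogOrCase, 0)
})

test_that("zero collapsed cells refuse unless the Haldane flag is set", {
  # all affected in cell (1,1), all unaffected in (3,1): c = d = 0
  co <- makeCohort(aff1 = rep(1L, 4L), aff2 = rep(1L, 4L),
                   un1 = rep(3L, 4L), un2 = rep(1L, 4L))
  expect_identical(gdsp(co, "s1", "s2")@status, "ZERO_CELL")
  resH <- gdsp(co, "s1", "s2", haldane = TRUE)
  expect_identical(resH@status, "OK")
  expect_true(is.finite(resH@gDsp))
})

test_that("genotype-concordant cohorts are degenerate, not testable", {
  co <- makeCohort(aff1 = c(1L, 2L, 3L), aff2 = c(2L, 2L, 2L),
                   un1 = c(1L, 2L, 3L), un2 = c(2L, 2L, 2L))
  expect_identical(gdsp(co, "s1", "s2")@status, "DEGENERATE")
})

test_that("exhaustive oracle reproduces the delta variance and the z-score", {
  co <- randomCohort(8L, seed = 21L, probs = c(1, 1, 1) / 3)
  o <- permutationOracle(co, 1L, 2L)
  cfg <- familyCellConfig(co, 1L, 2L)
  tb <- buildGenotypeTables(co, 1L, 2L)
  v <- varLogOrCase(tb$affected, cfg$u, cfg$v)
  # linearized enumeration moments match the closed form exactly
  expect_equal(o$linVarCase, as.numeric(v), tolerance = 1e-12)
  expect_equal(o$linVarDiff, 4 * as.numeric(v), tolerance = 1e-12)
  # the statistic equals the oracle z-score to >= 6 significant digits
  g <- gdsp(co, 1L, 2L)
  expect_equal(g@gDsp, o$observedDiff / sqrt(o$linVarDiff),
               tolerance = 1e-9)
})

test_that("label-swap covariance identity holds under the null", {
  co <- randomCohort(12L, seed = 33L, probs = c(1, 1, 1) / 3)
  o <- permutationOracle(co, 1L, 2L)
  # exact for the linearized log odds ratios (all 2^k assignments)
  expect_equal(o$linCov, -o$linVarCase, tolerance = 1e-12)
  expect_equal(o$linVarCtrl, o$linVarCase, tolerance = 1e-12)
  # approximate for the raw log odds ratios
  expect_equal(o$cov, -o$varCase, tolerance = 0.25)
  expect_equal(o$varCtrl, o$varCase, tolerance = 0.25)
})

test_that("oracle modes: refusal above k = 20, Monte Carlo determinism", {
  co <- randomCohort(22L, seed = 2L)
  expect_error(permutationOracle(co, 1L, 2L, mode = "exhaustive"),
               "k > 20")
  o1 <- permutationOracle(co, 1L, 2L, mode = "monte_carlo",
                          nPerm = 500L, seed = 7L)
  o2 <- permutationOracle(co, 1L, 2L, mode = "monte_carlo",
                          nPerm = 500L, seed = 7L)
  expect_identical(o1, o2)
})

test_that("swapping all affection labels negates G exactly", {
  for (seed in 4:8) {
    co <- randomCohort(50L, seed = seed)
    swapped <- DspCohort(unaffGenotypes(co), affGenotypes(co),
                         markerInfo(co), co@family)
    a <- gdsp(co, 1L, 2L); b <- gdsp(swapped, 1L, 2L)
    expect_identical(a@status, b@status)
    if (a@status == "OK") {
      expect_equal(b@gDsp, -a@gDsp, tolerance = 1e-12)
      expect_equal(b@pValue, a@pValue, tolerance = 1e-12)
      expect_equal(b@varLogOrCase, a@varLogOrCase, tolerance = 1e-12)
    }
  }
})

test_that("flipping allele labels at one SNP negates G exactly", {
  for (seed in 4:8) {
    co <- randomCohort(50L, seed = seed)
    aff <- affGenotypes(co); una <- unaffGenotypes(co)
    aff[, 1L] <- 4L - aff[, 1L]; una[, 1L] <- 4L - una[, 1L]
    flipped <- DspCohort(aff, una, markerInfo(co), co@family)
    a <- gdsp(co, 1L, 2L); b <- gdsp(flipped, 1L, 2L)
    expect_equal(b@gDsp, -a@gDsp, tolerance = 1e-12)
    expect_equal(b@pValue, a@pValue, tolerance = 1e-12)
  }
})

test_that("the statistic is symmetric in SNP order", {
  for (seed in 4:8) {
    co <- randomCohort(50L, seed = seed)
    a <- gdsp(co, 1L, 2L); b <- gdsp(co, 2L, 1L)
    expect_equal(b@gDsp, a@gDsp, tolerance = 1e-12)
    expect_equal(b@varLogOrCase, a@varLogOrCase, tolerance = 1e-12)
  }
})
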