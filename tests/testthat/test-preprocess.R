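test_that("exposure integration recovers exact and noisy linear responses", {
  t <- c(10, 20, 50, 100, 200)
  exact <- data.frame(peptide = "P1_1_15", exposure = t, intensity = 10 * t)
  out <- integrateExposures(exact)
  expect_equal(out$signal, 1000)
  expect_equal(out$r2, 1)

  flat <- data.frame(peptide = "P1_1_15", exposure = t, intensity = 50)
  out <- integrateExposures(flat, epsilon = 1)
  expect_equal(out$signal, 1)    # floored: zero slope
  expect_equal(out$r2, 0)        # no exposure response

  set.seed(101)
  y <- 3 * t + 20 + rnorm(5, sd = 5)
  noisy <- data.frame(peptide = "P1_1_15", exposure = t, intensity = y)
  out <- integrateExposures(noisy)
  ref <- oracleOls(t, y)
  expect_equal(out$signal, ref$slope * 100, tolerance = 1e-9)
  expect_equal(out$r2, ref$r2, tolerance = 1e-9)
})

test_that("exposure integration demands two distinct exposures", {
  one <- data.frame(peptide = "P1_1_15", exposure = c(50, 50),
                    intensity = c(5, 6))
  expect_error(integrateExposures(one), "distinct exposures")
  expect_error(
    integrateExposures(data.frame(peptide = "P1_1_15", exposure = 50,
                                  intensity = 5)),
    "distinct exposures")
})

test_that("log transform is exact log2 above the floor", {
  expect_equal(logTransform(1024), 10)
  expect_equal(logTransform(1), 0)
  set.seed(5)
  x <- runif(50, 1, 1e4)
  expect_equal(logTransform(x), log(x) / log(2), tolerance = 1e-12)
})

test_that("date centering matches the loop oracle, is idempotent, spares excluded", {
  m <- matrix(c(4, 6), 1, 2, dimnames = list("p", c("a", "b")))
  expect_equal(unname(dateCenter(m, c("d1", "d1"))), matrix(c(-1, 1), 1))

  set.seed(7)
  x <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("p%d", 1:5), sprintf("s%d", 1:12)))
  dates <- rep(c("d1", "d2", "d3"), each = 4)
  expect_equal(dateCenter(x, dates), oracleDateCenter(x, dates))
  expect_equal(dateCenter(dateCenter(x, dates), dates),
               dateCenter(x, dates))

  one <- dateCenter(x, rep("d1", 12))
  expect_true(all(abs(rowSums(one)) < 1e-9))

  incl <- rep(TRUE, 12); incl[3] <- FALSE
  cen <- dateCenter(x, dates, included = incl)
  expect_equal(cen[, 3], x[, 3])
  expect_equal(cen[, incl], oracleDateCenter(x, dates, incl)[, incl])

  expect_error(dateCenter(x, dates, included = c(rep(FALSE, 4), rep(TRUE, 8))),
               "no included samples")
})

test_that("sample QC recovers a planted antibody failure and degrades gracefully", {
  set.seed(21)
  base <- matrix(rnorm(60 * 11, mean = 8, sd = 0.4), 60, 11)
  base[, 4] <- base[, 4] - log2(10)   # 10-fold attenuated antibody signal
  qc <- qcSamples(base)
  expect_true(qc$fail[4])
  expect_equal(sum(qc$fail), 1L)
  expect_match(qc$reason[4], "antibody")

  same <- matrix(5, 30, 6)
  expect_false(any(qcSamples(same)$fail))

  expect_warning(qc2 <- qcSamples(matrix(rnorm(20), 10, 2)), "skipped")
  expect_false(any(qc2$fail))
})

test_that("per-date sample QC still catches failures on top of batch offsets", {
  set.seed(22)
  dates <- rep(c("d1", "d2", "d3"), each = 4)
  x <- matrix(rnorm(80 * 12, 8, 0.3), 80, 12)
  x[, dates == "d2"] <- x[, dates == "d2"] - 1.5   # strong batch offset
  x[, 7] <- x[, 7] - log2(10)                      # failed sample inside d2
  qc <- qcSamples(x, runDate = dates)
  expect_true(qc$fail[7])
  expect_equal(sum(qc$fail), 1L)
})

test_that("peptide QC counts samples above the floor", {
  sig <- rbind(rep(1, 6), rep(100, 6))   # at floor / well above
  expect_equal(unname(qcPeptides(sig, epsilon = 1)), c(FALSE, TRUE))

  set.seed(31)
  sig <- matrix(sample(c(1, 50), 40 * 8, TRUE), 40, 8)
  pass <- qcPeptides(sig, epsilon = 1, f = 0.5)
  manual <- apply(sig, 1, function(r) sum(r > 1) / length(r) >= 0.5)
  expect_equal(unname(pass), manual)
})

test_that("group means match hand computation and the loop oracle", {
  m <- matrix(c(2, 4, 1, 1), 1, 4, dimnames = list("p", NULL))
  gm <- groupMeanMatrix(m, group = c("ET", "ET", "UT", "UT"))
  expect_equal(unname(gm), matrix(c(3, 1), 1))

  set.seed(41)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(sprintf("p%d", 1:20),
                                                    sprintf("s%d", 1:8)))
  g <- rep(c("ET", "UT"), 4)
  expect_equal(groupMeanMatrix(x, group = g), oracleGroupMeans(x, g))
  expect_error(groupMeanMatrix(x[, 1:4, drop = FALSE],
                               group = rep("ET", 4)), "UT")
})

test_that("assembled experiments are valid, centered per date, and order-invariant", {
  sim <- toyFixture()
  pe <- toyExperiment()
  expect_true(validObject(pe))
  expect_equal(chipType(pe), "PTK")
  expect_equal(provenance(pe)[1],
               "integrate_exposures(slope x 100 ms, floor 1 AU)")

  cd <- SummarizedExperiment::colData(pe)
  X <- SummarizedExperiment::assay(pe, "log2")
  for (d in unique(cd$run_date)) {
    cols <- cd$run_date == d & cd$qc_pass
    expect_true(all(abs(rowMeans(X[, cols, drop = FALSE])) < 1e-9))
  }

  ## permute samples before preprocessing, unpermute after
  set.seed(99)
  perm <- sample(nrow(sim$meta))
  pe2 <- phosphoExperiment(sim$spots, sim$meta[perm, ], sim$layout)
  expect_equal(SummarizedExperiment::assay(pe2, "log2")[, colnames(X)], X)

  ## pre-excluded samples are honoured and never centered
  meta3 <- sim$meta
  meta3$excluded[1] <- TRUE
  meta3$exclude_reason[1] <- "detection error"
  pe3 <- phosphoExperiment(sim$spots, meta3, sim$layout)
  cd3 <- SummarizedExperiment::colData(pe3)
  expect_false(cd3$qc_pass[1])
  expect_equal(cd3$qc_reason[1], "detection error")
  expect_equal(SummarizedExperiment::assay(pe3, "log2")[, 1],
               SummarizedExperiment::assay(pe3, "raw_log2")[, 1])
})
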