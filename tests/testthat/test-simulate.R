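test_that("a null configuration with no noise produces identical samples", {
  cfg <- simConfig(nET = 3, nUT = 3, nPeptides = 10, noiseSd = 0,
                   dateEffectSd = 0, measurementNoiseSd = 0,
                   baselineLog2Sd = 0.5, nKinases = 2, seed = 5)
  sim <- simulateExperiment(cfg)
  pe <- suppressWarnings(phosphoExperiment(sim$spots, sim$meta, sim$layout))
  X <- SummarizedExperiment::assay(pe, "raw_log2")
  expect_true(all(abs(X - X[, 1]) < 1e-9))
  dp <- peptideDeltas(pe)
  expect_true(all(abs(deltas(dp)) < 1e-9))
})

test_that("simulation is byte-reproducible from its seed", {
  cfg <- simConfig(nET = 4, nUT = 4, nPeptides = 16, nKinases = 3, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateExperiment(cfg), d1)
  writeSimulation(simulateExperiment(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("planted iviv effects appear at the configured contrast size", {
  cfg <- simConfig(planted = c(KIN01 = 1.0), nKinases = 6, seed = 13)
  sim <- simulateExperiment(cfg)
  pe <- phosphoExperiment(sim$spots, sim$meta, sim$layout)
  ev <- sim$evidence
  iviv <- ev$peptide[ev$kinase == "KIN01" & ev$rank == 0L]
  others <- setdiff(names(which(sim$truth$effect == 0)), iviv)
  dp <- deltas(peptideDeltas(pe))
  ## mean contrast on the 5 planted iviv substrates: effect 1.0, noise 0.5,
  ## n = 12 vs 13 -> SE = 0.5 sqrt(1/12 + 1/13) / sqrt(5)
  se <- 0.5 * sqrt(1 / 12 + 1 / 13) / sqrt(length(iviv))
  expect_lt(abs(mean(dp[iviv]) - 1.0), 3 * se + 0.05)
  expect_lt(abs(mean(dp[others])), 0.2)
})

test_that("rank attenuation scales the planted effect transmitted per peptide", {
  ev <- data.frame(kinase = "K1",
                   peptide = sprintf("TKS%03d_101_115", 1:4),
                   source = c("iviv", rep("insilico", 3)),
                   rank = c(0L, 2L, 6L, 12L))
  cfg <- simConfig(planted = c(K1 = 1), nPeptides = 6, nKinases = 1,
                   evidence = ev, rankAttenuation = 0.85, seed = 3)
  sim <- simulateExperiment(cfg)
  expect_equal(unname(sim$truth$effect[ev$peptide]),
               0.85^c(0, 2, 6, 12))
  expect_error(
    simulateExperiment(simConfig(planted = c(NOPE = 1), evidence = ev,
                                 nPeptides = 6, nKinases = 1)),
    "NOPE")
})

test_that("noise-free intensities are exactly linear in exposure and recover 2^x", {
  cfg <- simConfig(nET = 2, nUT = 2, nPeptides = 8, measurementNoiseSd = 0,
                   nKinases = 2, nDates = 1, seed = 21)
  sim <- simulateExperiment(cfg)
  s1 <- sim$meta$sample_id[1]
  out <- integrateExposures(sim$spots[sim$spots$sample == s1, ])
  expect_true(all(out$r2 >= 0.99))
  ## recover the latent log2 signal within 1%
  rate <- out$signal
  sub <- sim$spots[sim$spots$sample == s1 & sim$spots$exposure == 100, ]
  expect_equal(rate[match(sub$peptide, out$peptide)] / sub$intensity,
               rep(1, nrow(sub)), tolerance = 0.01)
})

test_that("date centering removes at least 90% of the date-attributable variance", {
  cfg <- simConfig(dateEffectSd = 1, noiseSd = 0.3, nKinases = 4, seed = 31)
  sim <- simulateExperiment(cfg)
  pe <- phosphoExperiment(sim$spots, sim$meta, sim$layout)
  raw <- SummarizedExperiment::assay(pe, "raw_log2")
  cen <- SummarizedExperiment::assay(pe, "log2")
  dateVar <- function(m) {
    med <- apply(m, 2, median)
    stats::var(tapply(med, sim$meta$run_date, mean))
  }
  expect_lt(dateVar(cen), 0.1 * dateVar(raw))
})

test_that("failed samples are attenuated tenfold and caught by QC", {
  cfg <- simConfig(failedSamples = "UT05", nKinases = 4, seed = 41)
  sim <- simulateExperiment(cfg)
  pe <- phosphoExperiment(sim$spots, sim$meta, sim$layout)
  cd <- SummarizedExperiment::colData(pe)
  expect_false(cd["UT05", "qc_pass"])
  expect_match(cd["UT05", "qc_reason"], "antibody")
  expect_equal(sum(!cd$qc_pass), 1L)
})

test_that("the toy fixture is deterministic, QC-clean, and separable by enumeration", {
  sim <- toyFixture()
  sim2 <- makeToyFixture()
  expect_identical(sim$spots, sim2$spots)
  expect_identical(sim$truth, sim2$truth)

  pe <- toyExperiment()
  expect_true(all(SummarizedExperiment::colData(pe)$qc_pass))
  expect_true(all(SummarizedExperiment::rowData(pe)$qc_pass))

  ## exact-enumeration significance: planted kinase beats the null kinase
  X <- SummarizedExperiment::assay(pe, "log2")[scoringPeptides(pe), ]
  g <- SummarizedExperiment::colData(pe)$group
  map <- buildSubstrateMap(sim$evidence, pe)
  qUp <- significanceScore(X, substrateSet(map, "KUP", 0), group = g)
  qNull <- significanceScore(X, substrateSet(map, "KNULL", 12), group = g)
  expect_true(qUp$exact && qNull$exact)
  expect_gt(qUp$Qsg, qNull$Qsg)
})
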