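test_that("peptide deltas are signed ET-minus-UT group mean contrasts", {
  X <- rbind(p1_1_15 = c(2, 2, 1, 1), p2_1_15 = c(0, 0, 3, 3))
  pe <- makeMatrixPE(X, group = c("ET", "ET", "UT", "UT"))
  dp <- peptideDeltas(pe)
  expect_equal(unname(deltas(dp)), c(1, -3))
  expect_equal(normalizer(dp), 3)

  Xn <- rbind(p1_1_15 = c(1, 1, 1, 1))
  dpn <- peptideDeltas(makeMatrixPE(Xn, group = c("ET", "ET", "UT", "UT")))
  expect_equal(unname(deltas(dpn)), 0)
  expect_equal(normalizer(dpn), 0)

  expect_error(peptideDeltas(makeMatrixPE(X[, 1:3], c("ET", "UT", "UT"))),
               "at least 2")
})

test_that("deltas on random data match a per-peptide loop oracle", {
  set.seed(55)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("p%02d_1_15", 1:50), NULL))
  g <- rep(c("ET", "UT"), each = 5)
  dp <- peptideDeltas(makeMatrixPE(X, g))
  manual <- sapply(seq_len(50), function(p)
    mean(X[p, g == "ET"]) - mean(X[p, g == "UT"]))
  expect_equal(unname(deltas(dp)), manual)
  expect_equal(normalizer(dp), max(abs(manual)))
})

test_that("the kinase statistic is the normalized set median, in [-1, 1]", {
  d <- c(a = 0.5, b = 0.5, c = 0.5, e = -0.1)
  dp <- new("DeltaProfile", delta = d, normalizer = max(abs(d)))
  expect_equal(kinaseStatistic(dp, c("a", "b", "c")), 1)   # saturating

  d2 <- c(a = -0.4, b = 0, c = 0.4, e = 0.4)
  dp2 <- new("DeltaProfile", delta = d2, normalizer = 0.4)
  expect_equal(kinaseStatistic(dp2, c("a", "b", "c")), 0)  # symmetric median

  set.seed(66)
  d3 <- setNames(rnorm(40), sprintf("p%02d", 1:40))
  dp3 <- new("DeltaProfile", delta = d3, normalizer = max(abs(d3)))
  for (sz in c(3, 7, 15)) {
    set <- sample(names(d3), sz)
    expect_equal(kinaseStatistic(dp3, set),
                 median(d3[set]) / max(abs(d3)), tolerance = 1e-12)
    expect_lte(abs(kinaseStatistic(dp3, set)), 1)
  }
  expect_error(kinaseStatistic(dp3, character()), "empty")
  expect_error(kinaseStatistic(dp3, "nope"), "outside")
})

test_that("specificity score handles the extreme and degenerate cases exactly", {
  d <- setNames(c(0.1, 0.2, 0.15, 0.12, 0.18, 1), sprintf("p%d", 1:6))
  dp <- new("DeltaProfile", delta = d, normalizer = 1)
  ## sObs beyond any achievable subset median of size 3
  out <- specificityScore(dp, setSize = 3, sObs = 0.99, K = 99, seed = 1)
  expect_equal(out$r, 0)
  expect_equal(out$Qsp, 2)

  ## whole universe: every random set is the universe itself
  sAll <- median(d) / 1
  out2 <- specificityScore(dp, setSize = 6, sObs = sAll, K = 99, seed = 1)
  expect_equal(out2$r, 99)
  expect_equal(out2$Qsp, 0)

  expect_error(specificityScore(dp, setSize = 7, sObs = 0, K = 9),
               "exceeds")
})

test_that("sampled specificity converges to the exhaustive-subset null", {
  set.seed(77)
  d <- setNames(rnorm(6), sprintf("p%d", 1:6))
  dp <- new("DeltaProfile", delta = d, normalizer = max(abs(d)))
  K <- 10000
  for (alt in c("two.sided", "directional")) {
    sObs <- median(d[c(1, 3, 5)]) / max(abs(d))
    pExact <- oracleExactQspP(unname(d), 3, sObs, alternative = alt)
    out <- specificityScore(dp, setSize = 3, sObs = sObs, K = K, seed = 42,
                            alternative = alt)
    se <- sqrt(pExact * (1 - pExact) / K)
    ## r ~ Binomial(K, pExact); compare on the probability scale
    expect_lt(abs(out$r / K - pExact), 3 * se + 1e-9)
  }
})

test_that("significance score enumerates small cohorts exactly", {
  set.seed(88)
  X <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(sprintf("p%d_1_15", 1:8), NULL))
  X[1:4, 1:3] <- X[1:4, 1:3] + 1.2
  g <- rep(c("ET", "UT"), each = 3)
  out <- significanceScore(X, peptides = rownames(X)[1:4], group = g)
  expect_true(out$exact)
  expect_equal(out$nPerm, choose(6, 3))
  ref <- oracleExactQsg(X, g, 1:4)
  expect_equal(out$p, ref$p)
  expect_equal(out$Qsg, ref$Qsg)
  expect_equal(out$sObs, ref$sObs)

  zero <- matrix(0, 5, 6, dimnames = list(sprintf("z%d", 1:5), NULL))
  out0 <- significanceScore(zero, peptides = c("z1", "z2", "z3"), group = g)
  expect_equal(out0$p, 1)
  expect_equal(out0$Qsg, 0)
})

test_that("sampled significance agrees across seeds and with enumeration", {
  set.seed(90)
  X <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(sprintf("p%02d_1_15", 1:12), NULL))
  X[1:5, 1:4] <- X[1:5, 1:4] + 1.5
  g <- rep(c("ET", "UT"), each = 4)
  set <- rownames(X)[1:5]
  exact <- significanceScore(X, set, group = g)     # C(8,4)=70 enumerated
  s1 <- significanceScore(X, set, group = g, B = 9999, seed = 1,
                          exactThreshold = 1)
  s2 <- significanceScore(X, set, group = g, B = 9999, seed = 2,
                          exactThreshold = 1)
  expect_false(s1$exact)
  expect_lt(abs(s1$Qsg - s2$Qsg), 0.1)
  se <- 3 * sqrt(exact$p * (1 - exact$p) / 9999)
  expect_lt(abs(s1$p - exact$p), se + 2 / 10000)
})

test_that("per-cutoff final scores satisfy Q_t = Qsg_t + Qsp_t and s stays bounded", {
  run <- plantedRun(seed = 7)
  ss <- scoreKinases(run$pe, run$map, seed = 7, K = 199, B = 199)
  tr <- cutoffTrace(ss)
  expect_gt(nrow(tr), 0)
  expect_equal(tr$Q_t, tr$Qsg_t + tr$Qsp_t, tolerance = 0)
  expect_true(all(abs(tr$s_t) <= 1))
  expect_true(all(tr$Qsg_t >= 0 & tr$Qsp_t >= 0))
  sc <- kinaseScores(ss)
  expect_true(all(abs(sc$s) <= 1))
  expect_equal(sc$relevant, sc$Qsp > 1.3)
})

test_that("a kinase with a single valid cutoff reports that cutoff's values", {
  pe <- toyExperiment()
  ev <- data.frame(kinase = "KSOLO",
                   peptide = scoringPeptides(pe)[1:3],
                   source = "iviv", rank = 0L)
  map <- buildSubstrateMap(ev, pe)
  res <- scoreKinase(pe, map, "KSOLO", cutoffs = c(0L), K = 99, seed = 3)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$score$s, res$trace$s_t)
  expect_equal(res$score$Q, res$trace$Q_t)
  expect_equal(res$score$n_peptides_median, 3L)
})

test_that("planted directions are recovered on the toy fixture and flip with sign", {
  pe <- toyExperiment()
  sim <- toyFixture()
  map <- buildSubstrateMap(sim$evidence, pe)
  ss <- scoreKinases(pe, map, seed = 11)
  sc <- kinaseScores(ss)
  expect_gt(sc$s[sc$kinase == "KUP"], 0)
  expect_lt(sc$s[sc$kinase == "KDOWN"], 0)
  expect_true(sc$relevant[sc$kinase == "KUP"])
  expect_true(sc$relevant[sc$kinase == "KDOWN"])
  expect_gt(min(sc$Q[sc$kinase %in% c("KUP", "KDOWN")]),
            sc$Q[sc$kinase == "KNULL"])

  ## swapping group labels negates s and leaves both scores unchanged
  meta2 <- sim$meta
  meta2$group <- ifelse(meta2$group == "ET", "UT", "ET")
  pe2 <- phosphoExperiment(sim$spots, meta2, sim$layout)
  ss2 <- scoreKinases(pe2, buildSubstrateMap(sim$evidence, pe2), seed = 11)
  sc2 <- kinaseScores(ss2)
  m <- match(sc$kinase, sc2$kinase)
  expect_equal(sc2$s[m], -sc$s)
  expect_equal(sc2$Qsp[m], sc$Qsp)
  expect_equal(sc2$Qsg[m], sc$Qsg)
})

test_that("scores are invariant to sample order given the same seed", {
  sim <- toyFixture()
  pe <- toyExperiment()
  map <- buildSubstrateMap(sim$evidence, pe)
  ref <- kinaseScores(scoreKinases(pe, map, seed = 4, K = 199))
  set.seed(1); perm <- sample(nrow(sim$meta))
  pe2 <- phosphoExperiment(sim$spots, sim$meta[perm, ], sim$layout)
  got <- kinaseScores(scoreKinases(pe2, buildSubstrateMap(sim$evidence, pe2),
                                   seed = 4, K = 199))
  expect_equal(got, ref)
})

test_that("ranking is by Q with Qsp then name as tie-breaks", {
  sc <- data.frame(kinase = c("B", "A", "C", "D"),
                   s = 0.1, Qsg = 1, Qsp = c(2.65, 2.43, 2.43, 1.0),
                   Q = c(3.92, 3.92, 3.92, 2.0),
                   n_peptides_median = 4L, relevant = TRUE)
  expect_equal(rankKinases(sc)$kinase, c("B", "A", "C", "D"))
  sc$Qsp[1] <- 2.43
  expect_equal(rankKinases(sc)$kinase, c("A", "B", "C", "D"))
})

test_that("kinases without a large enough substrate set are reported unscored", {
  pe <- toyExperiment()
  ev <- data.frame(kinase = c("KTINY", "KTINY"),
                   peptide = scoringPeptides(pe)[1:2],
                   source = "iviv", rank = 0L)
  map <- buildSubstrateMap(ev, pe)
  ss <- scoreKinases(pe, map, seed = 1)
  expect_equal(ss@unscored, "KTINY")
  expect_equal(nrow(kinaseScores(ss)), 0L)
})
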