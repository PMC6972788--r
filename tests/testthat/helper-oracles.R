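## Independent oracles and shared fixtures. Oracles are deliberately written
## as explicit loops / enumeration, independent of the package's vectorised
## code paths.

# ordinary least squares slope/intercept/R2 via explicit normal equations
oracleOls <- function(t, y) {
  A <- cbind(1, t)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  fit <- A %*% beta
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1L], slope = beta[2L],
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

# per-date per-peptide centering with explicit loops
oracleDateCenter <- function(x, dates, included = rep(TRUE, ncol(x))) {
  out <- x
  for (p in seq_len(nrow(x))) {
    for (d in unique(dates)) {
      cols <- which(dates == d & included)
      out[p, cols] <- x[p, cols] - mean(x[p, cols])
    }
  }
  out
}

oracleGroupMeans <- function(x, group) {
  gs <- sort(unique(group))
  out <- matrix(NA_real_, nrow(x), length(gs),
                dimnames = list(rownames(x), gs))
  for (p in seq_len(nrow(x)))
    for (j in seq_along(gs))
      out[p, j] <- mean(x[p, group == gs[j]])
  out
}

# exact specificity null: probability over all C(n, setSize) peptide subsets
oracleExactQspP <- function(delta, setSize, sObs,
                            alternative = "two.sided") {
  nrm <- max(abs(delta))
  subs <- utils::combn(length(delta), setSize)
  sr <- apply(subs, 2L, function(ix) stats::median(delta[ix])) / nrm
  if (alternative == "two.sided") mean(abs(sr) >= abs(sObs) - 1e-12)
  else if (sObs >= 0) mean(sr >= sObs - 1e-12)
  else mean(sr <= sObs + 1e-12)
}

# exact permutation null of |s| by full enumeration of label assignments
oracleExactQsg <- function(X, group, peptideIdx) {
  n <- ncol(X)
  n1 <- sum(group == "ET")
  stat <- function(labs) {
    d <- numeric(nrow(X))
    for (p in seq_len(nrow(X)))
      d[p] <- mean(X[p, labs == "ET"]) - mean(X[p, labs == "UT"])
    nrm <- max(abs(d))
    if (nrm == 0) 0 else stats::median(d[peptideIdx]) / nrm
  }
  sObs <- stat(group)
  combs <- utils::combn(n, n1)
  vals <- apply(combs, 2L, function(ix) {
    labs <- rep("UT", n); labs[ix] <- "ET"; stat(labs)
  })
  b <- sum(abs(vals) >= abs(sObs) - 1e-12)
  list(p = b / ncol(combs), Qsg = -log10(b / ncol(combs)), sObs = sObs)
}

# minimal PhosphoExperiment straight from a log2 matrix (all QC passing)
makeMatrixPE <- function(X, group, runDate = rep("D01", ncol(X)),
                         chipType = "PTK") {
  stopifnot(!is.null(rownames(X)))
  colnames(X) <- colnames(X) %||% sprintf("S%02d", seq_len(ncol(X)))
  rd <- S4Vectors::DataFrame(raw = rownames(X), is_control = FALSE,
                             qc_pass = TRUE, row.names = rownames(X))
  cd <- S4Vectors::DataFrame(sample_id = colnames(X), group = group,
                             run_date = runDate, qc_pass = TRUE,
                             qc_reason = "", row.names = colnames(X))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = X), rowData = rd, colData = cd,
    metadata = list(chipType = chipType, epsilon = 1, provenance = "test"))
  new("PhosphoExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy fixture, generated once per test run
.fixtureCache <- new.env(parent = emptyenv())

toyFixture <- function() {
  if (is.null(.fixtureCache$sim)) .fixtureCache$sim <- makeToyFixture()
  .fixtureCache$sim
}

toyExperiment <- function() {
  if (is.null(.fixtureCache$pe)) {
    sim <- toyFixture()
    .fixtureCache$pe <- phosphoExperiment(sim$spots, sim$meta, sim$layout)
  }
  .fixtureCache$pe
}

# a small but realistic planted-effect dataset reused by several files
plantedRun <- function(seed = 42, nKinases = 8) {
  cfg <- simConfig(planted = c(KIN03 = 1.0), nKinases = nKinases,
                   seed = seed)
  sim <- simulateExperiment(cfg)
  pe <- phosphoExperiment(sim$spots, sim$meta, sim$layout)
  list(sim = sim, pe = pe,
       map = buildSubstrateMap(sim$evidence, pe))
}
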