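## Synthetic experiment generator. Emulates the statistical structure the
## analysis assumes: log2-scale peptide baselines, run-date batch offsets,
## additive planted group effects transmitted to substrate peptides with
## rank-dependent attenuation, linear fluorescence response over camera
## exposure times, and occasional failed samples with globally attenuated
## antibody signal.

#' Simulation configuration
#'
#' Defaults mirror the study design this pipeline targets: 12
#' endurance-trained (ET) vs 13 untrained (UT) subjects, three run dates
#' with groups stratified evenly across dates, a tyrosine chip of 144
#' substrate peptides, end-level reads at exposures 10/20/50/100/200 ms.
#'
#' @param chipType `"PTK"` (default) or `"STK"`.
#' @param nET,nUT group sizes (defaults 12 and 13).
#' @param nDates number of run dates (default 3); samples are assigned
#'   round-robin within group, so groups stay balanced across dates.
#' @param nPeptides number of substrate peptides; default is the canonical
#'   chip geometry (144 PTK / 140 STK; STK additionally gets its 4 control
#'   peptides).
#' @param baselineLog2Mean,baselineLog2Sd per-peptide baseline log2 signal
#'   distribution (defaults 8 and 1, i.e. around 256 AU).
#' @param noiseSd residual log2 noise per spot (default 0.5).
#' @param dateEffectSd standard deviation of the per-sample run-date batch
#'   offset on the log2 scale (default 0.5).
#' @param planted named numeric vector of per-kinase activity effects in
#'   log2 units (positive = more active in ET); names must be kinases of the
#'   evidence map.
#' @param rankAttenuation multiplicative transmission loss per in-silico
#'   evidence rank step (default 0.85): a planted effect `e` reaches a
#'   rank-`r` substrate as `e * rankAttenuation^r`.
#' @param exposures end-level camera exposure times in ms.
#' @param measurementNoiseSd relative (multiplicative) measurement noise on
#'   spot intensities (default 0.01).
#' @param failedSamples sample ids whose raw intensities are multiplied by
#'   0.1, emulating insufficient antibody binding.
#' @param nKinases,nIviv,nInsilico evidence-map generation: number of
#'   kinases, iviv (rank 0) substrates and in-silico (rank 1-12) substrates
#'   per kinase.
#' @param evidence optional evidence data.frame overriding generation.
#' @param balancedDates logical; `FALSE` assigns dates adversarially
#'   (groups confounded with date) for robustness experiments.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return a `SimConfig` (validated named list).
#' @export
simConfig <- function(chipType = c("PTK", "STK"), nET = 12, nUT = 13,
                      nDates = 3, nPeptides = NULL,
                      baselineLog2Mean = 8, baselineLog2Sd = 1,
                      noiseSd = 0.5, dateEffectSd = 0.5,
                      planted = numeric(), rankAttenuation = 0.85,
                      exposures = c(10, 20, 50, 100, 200),
                      measurementNoiseSd = 0.01,
                      failedSamples = character(),
                      nKinases = 20, nIviv = 5, nInsilico = 8,
                      evidence = NULL, balancedDates = TRUE, seed = 1) {
  chipType <- match.arg(chipType)
  if (is.null(nPeptides))
    nPeptides <- .CANONICAL_LAYOUT[[chipType]][["substrates"]]
  cfg <- list(chipType = chipType, nET = as.integer(nET),
              nUT = as.integer(nUT), nDates = as.integer(nDates),
              nPeptides = as.integer(nPeptides),
              baselineLog2Mean = baselineLog2Mean,
              baselineLog2Sd = baselineLog2Sd, noiseSd = noiseSd,
              dateEffectSd = dateEffectSd, planted = planted,
              rankAttenuation = rankAttenuation, exposures = exposures,
              measurementNoiseSd = measurementNoiseSd,
              failedSamples = failedSamples,
              nKinases = as.integer(nKinases), nIviv = as.integer(nIviv),
              nInsilico = as.integer(nInsilico), evidence = evidence,
              balancedDates = isTRUE(balancedDates),
              seed = as.integer(seed))
  stopifnot(cfg$nET >= 2, cfg$nUT >= 2, cfg$nDates >= 1,
            cfg$baselineLog2Sd >= 0, cfg$noiseSd >= 0,
            cfg$dateEffectSd >= 0, cfg$measurementNoiseSd >= 0,
            all(is.finite(cfg$planted)),
            cfg$rankAttenuation > 0, cfg$rankAttenuation <= 1,
            length(cfg$exposures) >= 2, all(cfg$exposures > 0))
  class(cfg) <- "SimConfig"
  cfg
}

## peptide id grammar for simulated chips: 15-mer ranges
.simLayout <- function(chipType, nPeptides) {
  prefix <- if (chipType == "PTK") "TKS" else "SKS"
  ids <- sprintf("%s%03d_%d_%d", prefix, seq_len(nPeptides), 101L, 115L)
  controls <- if (chipType == "STK") sprintf("ART_CTRL_%d", 1:4) else
    character()
  makeChipLayout(c(ids, controls), chipType = chipType, controls = controls,
                 strict = TRUE)
}

.simEvidence <- function(cfg, substrates) {
  kin <- sprintf("KIN%02d", seq_len(cfg$nKinases))
  rows <- lapply(kin, function(k) {
    iviv <- sample(substrates, min(cfg$nIviv, length(substrates)))
    rest <- setdiff(substrates, iviv)
    insil <- sample(rest, min(cfg$nInsilico, length(rest)))
    data.frame(
      kinase = k,
      peptide = c(iviv, insil),
      source = c(rep("iviv", length(iviv)), rep("insilico", length(insil))),
      rank = c(rep(0L, length(iviv)),
               sample(1:12, length(insil), replace = TRUE)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic experiment
#'
#' Generative model (log2 scale): peptide baseline
#' `b_p ~ N(baselineLog2Mean, baselineLog2Sd)`; run-date batch offset
#' `d ~ N(0, dateEffectSd)`, one draw per date, shared by all samples
#' processed on that date (this is what date centering removes); planted
#' group effect reaching
#' peptide p as the sum over planted kinases targeting p of
#' `effect * rankAttenuation^rank`; spot-level log2 signal
#' `x_ps = b_p + d_s + [s in ET] * effect_p + N(0, noiseSd)`. Raw
#' fluorescence at exposure `t` ms is `(2^x_ps / 100) * t` times small
#' multiplicative measurement noise, so exposure integration recovers
#' `2^x_ps` as the 100 ms-equivalent signal. Samples listed in
#' `failedSamples` have all intensities multiplied by 0.1. Control peptides
#' (STK chips) get a constant high baseline and no group effect.
#'
#' @param config a [simConfig()].
#' @return list with elements `spots` (spot reading data.frame), `meta`
#'   (sample metadata), `evidence` (kinase-substrate table), `layout`
#'   ([ChipLayout]), `truth` (list: per-peptide `effect`, `planted`,
#'   `failedSamples`, per-sample `date`), and `config`.
#' @export
simulateExperiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  set.seed(cfg$seed)

  layout <- .simLayout(cfg$chipType, cfg$nPeptides)
  pep <- peptides(layout)
  substrates <- pep$raw[!pep$is_control]

  evidence <- cfg$evidence %||% .simEvidence(cfg, substrates)
  validateEvidence(evidence)
  evidence <- dedupEvidence(evidence)
  unknownPlanted <- setdiff(names(cfg$planted), evidence$kinase)
  if (length(unknownPlanted))
    stop(sprintf("planted kinase(s) absent from the evidence map: %s",
                 paste(sQuote(unknownPlanted), collapse = ", ")),
         call. = FALSE)

  ## per-peptide planted effect, attenuated by evidence rank
  effect <- stats::setNames(rep(0, length(substrates)), substrates)
  for (k in names(cfg$planted)) {
    rows <- evidence[evidence$kinase == k, ]
    effect[rows$peptide] <- effect[rows$peptide] +
      cfg$planted[[k]] * cfg$rankAttenuation^rows$rank
  }

  sampleIds <- c(sprintf("ET%02d", seq_len(cfg$nET)),
                 sprintf("UT%02d", seq_len(cfg$nUT)))
  group <- rep(c("ET", "UT"), c(cfg$nET, cfg$nUT))
  dates <- sprintf("D%02d", seq_len(cfg$nDates))
  dateOf <- if (cfg$balancedDates) {
    ## round-robin within group keeps the ET fraction nearly constant per
    ## date, so date centering cannot erase the group contrast
    c(dates[((seq_len(cfg$nET) - 1L) %% cfg$nDates) + 1L],
      dates[((seq_len(cfg$nUT) - 1L) %% cfg$nDates) + 1L])
  } else {
    ## adversarial: fill dates sequentially, confounding group with date
    dates[pmin(ceiling(seq_along(sampleIds) /
                         ceiling(length(sampleIds) / cfg$nDates)),
               cfg$nDates)]
  }
  badFailed <- setdiff(cfg$failedSamples, sampleIds)
  if (length(badFailed))
    stop(sprintf("unknown failed sample id(s): %s",
                 paste(sQuote(badFailed), collapse = ", ")), call. = FALSE)

  nS <- length(sampleIds)
  baseline <- stats::rnorm(length(substrates), cfg$baselineLog2Mean,
                           cfg$baselineLog2Sd)
  dateShift <- stats::setNames(
    stats::rnorm(cfg$nDates, 0, cfg$dateEffectSd), dates)
  X <- matrix(baseline, length(substrates), nS) +
    matrix(dateShift[dateOf], length(substrates), nS, byrow = TRUE) +
    outer(effect, as.numeric(group == "ET")) +
    matrix(stats::rnorm(length(substrates) * nS, 0, cfg$noiseSd),
           length(substrates), nS)
  dimnames(X) <- list(substrates, sampleIds)
  if (any(pep$is_control)) {
    ctrl <- matrix(cfg$baselineLog2Mean + 2, sum(pep$is_control), nS,
                   dimnames = list(pep$raw[pep$is_control], sampleIds))
    X <- rbind(X, ctrl)[pep$raw, , drop = FALSE]
  }

  expos <- cfg$exposures
  nP <- nrow(X)
  spots <- data.frame(
    sample = rep(sampleIds, each = nP * length(expos)),
    peptide = rep(rep(pep$raw, times = length(expos)), times = nS),
    cycle = 93L,
    exposure = rep(rep(expos, each = nP), times = nS),
    stringsAsFactors = FALSE)
  rate <- 2^X / 100                       # AU per ms
  intensity <- rate[cbind(match(spots$peptide, rownames(X)),
                          match(spots$sample, colnames(X)))] * spots$exposure
  if (cfg$measurementNoiseSd > 0)
    intensity <- intensity *
      (1 + stats::rnorm(length(intensity), 0, cfg$measurementNoiseSd))
  fail <- spots$sample %in% cfg$failedSamples
  intensity[fail] <- intensity[fail] * 0.1
  spots$intensity <- intensity

  meta <- data.frame(
    sample_id = sampleIds, group = group, run_date = dateOf,
    chip_id = sprintf("chip%02d", ceiling(seq_len(nS) / 4)),
    array_position = ((seq_len(nS) - 1L) %% 4L) + 1L,
    excluded = FALSE, exclude_reason = "",
    stringsAsFactors = FALSE)

  list(spots = spots, meta = meta, evidence = evidence, layout = layout,
       truth = list(effect = effect, planted = cfg$planted,
                    failedSamples = cfg$failedSamples,
                    date = stats::setNames(dateOf, sampleIds)),
       config = cfg)
}

#' Write a simulated experiment to disk
#'
#' Emits exactly the tabular formats the readers consume: `spots.tsv`,
#' `meta.tsv`, `evidence.tsv`, `layout.tsv`, plus the ground truth as
#' `truth.tsv`.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @param header optional comment lines prefixed to every file.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSpotTable(file.path(dir, "spots.tsv"), sim$spots, header = header)
  writeSampleMeta(file.path(dir, "meta.tsv"), sim$meta, header = header)
  writeEvidenceTable(file.path(dir, "evidence.tsv"), sim$evidence,
                     header = header)
  pep <- peptides(sim$layout)
  .writeTable(data.frame(peptide = pep$raw, is_control = pep$is_control),
              file.path(dir, "layout.tsv"), header = header)
  .writeTable(data.frame(peptide = names(sim$truth$effect),
                         effect = unname(sim$truth$effect)),
              file.path(dir, "truth.tsv"), header = header)
  invisible(dir)
}

#' Read a layout table written by writeSimulation
#'
#' @param path file path (`layout.tsv`: columns `peptide`, `is_control`).
#' @param chipType chip type of the layout.
#' @return a [ChipLayout].
#' @export
readLayoutTable <- function(path, chipType = c("PTK", "STK")) {
  chipType <- match.arg(chipType)
  df <- .readTable(path, required = c("peptide", "is_control"))
  makeChipLayout(df$peptide, chipType = chipType,
                 controls = df$peptide[as.logical(df$is_control)])
}

#' Bundled miniature fixture experiment
#'
#' A deterministic 24-peptide, 4 + 4 sample experiment with three kinases:
#' one planted up-regulated (`KUP`, four iviv substrates, +2 log2 units),
#' one planted down-regulated (`KDOWN`, four iviv substrates, -2), and one
#' null (`KNULL`, five mixed-rank substrates on unaffected peptides). Small
#' enough that the label-permutation null (C(8,4) = 70 assignments) and the
#' random-set null (C(24,4) subsets) can be enumerated exhaustively, yet
#' with enough unaffected peptides that the planted kinases clear the
#' specificity threshold; constructed so that every sample and peptide
#' passes quality control.
#'
#' @return as [simulateExperiment()].
#' @export
makeToyFixture <- function() {
  ids <- sprintf("TKS%03d_%d_%d", 1:24, 101L, 115L)
  evidence <- data.frame(
    kinase = c(rep("KUP", 4), rep("KDOWN", 4), rep("KNULL", 5)),
    peptide = c(ids[1:4], ids[5:8], ids[c(9, 12, 15, 18, 21)]),
    source = c(rep("iviv", 8), rep("iviv", 3), "insilico", "insilico"),
    rank = c(rep(0L, 11), 4L, 9L),
    stringsAsFactors = FALSE)
  cfg <- simConfig(chipType = "PTK", nET = 4, nUT = 4, nDates = 2,
                   nPeptides = 24, baselineLog2Mean = 8, baselineLog2Sd = 1,
                   noiseSd = 0.3, dateEffectSd = 0.3,
                   planted = c(KUP = 2, KDOWN = -2),
                   measurementNoiseSd = 0, evidence = evidence,
                   seed = 20200121L)
  simulateExperiment(cfg)
}
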