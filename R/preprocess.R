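## Preprocessing: multi-exposure signal integration, log transformation,
## sample/peptide quality control and run-date batch centering, assembled
## into a PhosphoExperiment.

#' Integrate multi-exposure spot readings into one signal per peptide
#'
#' At the end-level read cycle every spot is imaged at several camera
#' exposure times (canonically 10, 20, 50, 100 and 200 ms). Fluorescence is
#' modelled as linear in exposure time; per peptide an ordinary
#' least-squares line (with intercept) is fitted to intensity vs exposure
#' and the signal is reported as the fitted slope times 100 ms (a "100 ms
#' equivalent" intensity). Slopes at or below zero (blank or saturated
#' spots) are floored at `epsilon`. The fit's coefficient of determination
#' is returned for quality control; for spots with constant intensity
#' (zero intensity variance) R-squared is defined as 0.
#'
#' @param spots data.frame of spot readings for a single sample, columns
#'   `peptide`, `exposure`, `intensity` (a `cycle` column, if present, is
#'   reduced to its maximum = the end-level cycle).
#' @param epsilon signal floor in AU (default 1), applied before the log
#'   transform downstream.
#' @return data.frame with columns `peptide`, `signal`, `r2`.
#' @export
integrateExposures <- function(spots, epsilon = 1) {
  .assertColumns(spots, c("peptide", "exposure", "intensity"), "spot readings")
  if (!is.null(spots$sample) && length(unique(spots$sample)) > 1L)
    stop("integrateExposures() expects readings from a single sample",
         call. = FALSE)
  if (!is.null(spots$cycle)) spots <- spots[spots$cycle == max(spots$cycle), ]

  g <- factor(spots$peptide, levels = unique(spots$peptide))
  nExp <- tapply(spots$exposure, g, function(t) length(unique(t)))
  if (any(nExp < 2L))
    stop(sprintf("fewer than 2 distinct exposures for peptide(s): %s",
                 paste(sQuote(names(nExp)[nExp < 2L]), collapse = ", ")),
         call. = FALSE)

  t <- spots$exposure; y <- spots$intensity
  n <- as.vector(table(g))
  st <- as.vector(rowsum(t, g)); sy <- as.vector(rowsum(y, g))
  stt <- as.vector(rowsum(t * t, g)); sty <- as.vector(rowsum(t * y, g))
  syy <- as.vector(rowsum(y * y, g))
  sxx <- stt - st^2 / n
  sxy <- sty - st * sy / n
  syyc <- syy - sy^2 / n
  slope <- sxy / sxx
  r2 <- ifelse(syyc > 0, (sxy^2 / sxx) / syyc, 0)
  data.frame(peptide = levels(g),
             signal = pmax(slope * 100, epsilon),
             r2 = r2, stringsAsFactors = FALSE)
}

#' Log2-transform floored signals
#'
#' @param signals numeric vector/matrix of signals in AU, already floored at
#'   `epsilon` (values below the floor are raised to it defensively).
#' @param epsilon signal floor (default 1 AU, so the floor maps to 0).
#' @return log2 signals, same shape as the input.
#' @export
logTransform <- function(signals, epsilon = 1) {
  log2(pmax(signals, epsilon))
}

#' Flag failed samples
#'
#' A sample fails quality control when its median log2 signal over substrate
#' peptides falls more than `k` median absolute deviations below the cohort
#' (insufficient antibody binding) or when its median exposure-fit R-squared
#' falls below `rMin` (detection failure). When run dates are supplied the
#' dim-signal rule compares each sample against its own run date's median
#' level, because day-to-day batch offsets shift whole dates together and
#' are removed later by date centering -- antibody failure is a per-sample
#' event and must not flag an entire batch. With fewer than 3 assessable
#' samples the check is skipped with a warning.
#'
#' @param rawLog2 peptide x sample matrix of pre-centering log2 signals.
#' @param r2 matching matrix of exposure-fit R-squared values (or `NULL` to
#'   skip the fit-quality rule).
#' @param isControl logical vector flagging control-peptide rows.
#' @param preExcluded logical vector of samples excluded a priori.
#' @param runDate optional per-sample run dates for the within-batch
#'   comparison.
#' @param k MAD multiplier (default 3).
#' @param rMin minimum acceptable median R-squared (default 0.5).
#' @return list with logical `fail` and character `reason` per sample.
#' @export
qcSamples <- function(rawLog2, r2 = NULL, isControl = NULL,
                      preExcluded = NULL, runDate = NULL, k = 3,
                      rMin = 0.5) {
  ns <- ncol(rawLog2)
  if (is.null(isControl)) isControl <- rep(FALSE, nrow(rawLog2))
  if (is.null(preExcluded)) preExcluded <- rep(FALSE, ns)
  fail <- rep(FALSE, ns)
  reason <- rep("", ns)
  cohort <- which(!preExcluded)
  if (length(cohort) < 3L) {
    warning("fewer than 3 samples in the cohort; sample QC skipped",
            call. = FALSE)
    return(list(fail = fail, reason = reason))
  }
  sub <- rawLog2[!isControl, cohort, drop = FALSE]
  med <- apply(sub, 2L, stats::median)
  if (!is.null(runDate)) {
    d <- as.character(runDate)[cohort]
    med <- med - stats::ave(med, d, FUN = stats::median)
  }
  lo <- stats::median(med) - k * stats::mad(med)
  dim_fail <- med < lo
  fail[cohort[dim_fail]] <- TRUE
  reason[cohort[dim_fail]] <- "insufficient antibody binding (dim signal)"
  if (!is.null(r2)) {
    medr2 <- apply(r2[!isControl, cohort, drop = FALSE], 2L, stats::median)
    r2_fail <- medr2 < rMin
    fail[cohort[r2_fail]] <- TRUE
    reason[cohort[r2_fail]] <- trimws(paste(reason[cohort[r2_fail]],
                                            "poor exposure-response fit"))
  }
  list(fail = fail, reason = reason)
}

#' Flag low-signal peptides
#'
#' A peptide passes when its raw signal exceeds the floor `epsilon` in at
#' least a fraction `f` of the quality-passing samples. Control peptides are
#' never part of the scoring universe regardless of this mask.
#'
#' @param signal peptide x sample matrix of raw (pre-log) signals in AU.
#' @param included logical vector of samples to count over.
#' @param epsilon signal floor in AU.
#' @param f minimum fraction of included samples above the floor (default
#'   0.5).
#' @return logical vector, `TRUE` for passing peptides.
#' @export
qcPeptides <- function(signal, included = NULL, epsilon = 1, f = 0.5) {
  if (is.null(included)) included <- rep(TRUE, ncol(signal))
  sub <- signal[, included, drop = FALSE]
  rowMeans(sub > epsilon) >= f
}

#' Center log2 signals per peptide within run date
#'
#' Batch normalization: for each peptide and each run date, the mean over
#' that date's included samples is subtracted, removing day-to-day assay
#' offsets. Columns of excluded samples are left untouched. Idempotent.
#'
#' @param x peptide x sample matrix of log2 signals.
#' @param runDate per-sample run date (character or Date).
#' @param included logical vector of samples entering (and receiving) the
#'   centering; defaults to all.
#' @return matrix of the same shape with per-date peptide means equal to 0
#'   over included samples.
#' @export
dateCenter <- function(x, runDate, included = NULL) {
  if (length(runDate) != ncol(x))
    stop("runDate must have one entry per sample column", call. = FALSE)
  if (is.null(included)) included <- rep(TRUE, ncol(x))
  for (d in unique(as.character(runDate))) {
    cols <- which(as.character(runDate) == d & included)
    if (length(cols) == 0L)
      stop(sprintf("run date %s has no included samples", sQuote(d)),
           call. = FALSE)
    x[, cols] <- x[, cols, drop = FALSE] -
      rowMeans(x[, cols, drop = FALSE])
  }
  x
}

#' Per-group mean signal matrix
#'
#' @param x a [PhosphoExperiment] (assay `"log2"`, included samples only) or
#'   a peptide x sample matrix.
#' @param group per-sample group labels (ignored when `x` is a
#'   `PhosphoExperiment`).
#' @param included logical sample mask (ditto).
#' @return peptide x group matrix of arithmetic means.
#' @export
groupMeanMatrix <- function(x, group = NULL, included = NULL) {
  if (is(x, "PhosphoExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    group <- cd$group
    included <- cd$qc_pass
    x <- SummarizedExperiment::assay(x, "log2")
  }
  if (is.null(included)) included <- rep(TRUE, ncol(x))
  x <- x[, included, drop = FALSE]
  group <- group[included]
  for (gr in c("ET", "UT"))
    if (!gr %in% group)
      stop(sprintf("group %s has no included samples", gr), call. = FALSE)
  groups <- sort(unique(group))
  out <- matrix(NA_real_, nrow(x), length(groups),
                dimnames = list(rownames(x), groups))
  for (gr in groups) {
    cols <- group == gr
    if (!any(cols)) stop(sprintf("group %s has no included samples", gr),
                         call. = FALSE)
    out[, gr] <- rowMeans(x[, cols, drop = FALSE])
  }
  out
}

#' Assemble a PhosphoExperiment from spot readings
#'
#' Runs the full preprocessing chain: per-sample exposure integration
#' ([integrateExposures()]), flooring at `epsilon`, log2 transformation,
#' sample QC ([qcSamples()]), peptide QC ([qcPeptides()]) and per-peptide
#' date centering over included samples ([dateCenter()]). Samples already
#' marked `excluded` in the metadata never enter QC statistics or centering.
#'
#' @param spots spot readings data.frame (`sample`, `peptide`, `cycle`,
#'   `exposure`, `intensity`), e.g. from [readSpotTable()].
#' @param meta sample metadata data.frame (`sample_id`, `group`, `run_date`,
#'   optional `excluded`/`exclude_reason`), e.g. from [readSampleMeta()].
#' @param layout the [ChipLayout] the readings were made on.
#' @param epsilon signal floor in AU before the log transform (default 1).
#' @param qcK,qcRMin sample-QC parameters, see [qcSamples()].
#' @param qcF peptide-QC fraction, see [qcPeptides()].
#' @param center logical; apply date centering (default `TRUE`).
#' @return a [PhosphoExperiment].
#' @export
phosphoExperiment <- function(spots, meta, layout, epsilon = 1,
                              qcK = 3, qcRMin = 0.5, qcF = 0.5,
                              center = TRUE) {
  stopifnot(is(layout, "ChipLayout"))
  pep <- peptides(layout)
  samples <- meta$sample_id
  missingMeta <- setdiff(unique(spots$sample), samples)
  if (length(missingMeta))
    stop(sprintf("sample(s) without metadata: %s",
                 paste(sQuote(missingMeta), collapse = ", ")), call. = FALSE)

  signal <- matrix(NA_real_, nrow(pep), length(samples),
                   dimnames = list(pep$raw, samples))
  r2 <- signal
  for (s in samples) {
    one <- integrateExposures(spots[spots$sample == s, , drop = FALSE],
                              epsilon = epsilon)
    if (!setequal(one$peptide, pep$raw))
      stop(sprintf("sample %s: readings do not cover the layout exactly",
                   sQuote(s)), call. = FALSE)
    idx <- match(pep$raw, one$peptide)
    signal[, s] <- one$signal[idx]
    r2[, s] <- one$r2[idx]
  }

  rawLog2 <- logTransform(signal, epsilon)
  preExcluded <- if (is.null(meta$excluded)) rep(FALSE, length(samples)) else
    as.logical(meta$excluded)
  sq <- qcSamples(rawLog2, r2 = r2, isControl = pep$is_control,
                  preExcluded = preExcluded, runDate = meta$run_date,
                  k = qcK, rMin = qcRMin)
  included <- !preExcluded & !sq$fail
  reason <- ifelse(preExcluded,
                   if (is.null(meta$exclude_reason)) "excluded a priori" else
                     meta$exclude_reason,
                   sq$reason)

  pq <- qcPeptides(signal, included = included, epsilon = epsilon, f = qcF)
  centered <- if (center) dateCenter(rawLog2, meta$run_date, included) else
    rawLog2

  prov <- c(sprintf("integrate_exposures(slope x 100 ms, floor %g AU)", epsilon),
            "log2",
            sprintf("qc_samples(k=%g, rMin=%g)", qcK, qcRMin),
            sprintf("qc_peptides(f=%g)", qcF),
            if (center) "date_center(per peptide within run date)")

  cd <- S4Vectors::DataFrame(
    sample_id = samples, group = meta$group, run_date = meta$run_date,
    chip_id = meta$chip_id %||% NA_character_,
    array_position = meta$array_position %||% NA_integer_,
    qc_pass = included, qc_reason = reason,
    median_r2 = apply(r2[!pep$is_control, , drop = FALSE], 2L, stats::median),
    row.names = samples)
  rd <- S4Vectors::DataFrame(pep, qc_pass = pq, row.names = pep$raw)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = centered, raw_log2 = rawLog2, r2 = r2),
    rowData = rd, colData = cd,
    metadata = list(chipType = chipType(layout), epsilon = epsilon,
                    provenance = prov))
  new("PhosphoExperiment", se)
}

#' Scoring peptide universe of an experiment
#'
#' Quality-passing, non-control peptides: the universe over which contrasts,
#' random peptide sets and substrate maps are defined.
#'
#' @param pe a [PhosphoExperiment].
#' @return character vector of peptide identifiers.
#' @export
scoringPeptides <- function(pe) {
  rd <- SummarizedExperiment::rowData(pe)
  rownames(pe)[rd$qc_pass & !rd$is_control]
}
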