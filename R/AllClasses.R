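#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CHIP_TYPES <- c("PTK", "STK")

## canonical chip geometries: substrate / control spot counts
.CANONICAL_LAYOUT <- list(
  PTK = c(substrates = 144L, controls = 0L),
  STK = c(substrates = 140L, controls = 4L)
)

.PEPTIDE_COLS <- c("protein", "start", "end", "raw", "is_control")

#' ChipLayout: the set of peptides spotted on one array type
#'
#' A `ChipLayout` describes the peptides of one flow-through peptide
#' microarray: 15-mer substrate peptides representing putative
#' phosphorylation sites, plus (on serine/threonine chips) positive-control
#' peptides. Layouts need not have the canonical production geometry --
#' miniature layouts are used for simulation and testing; use
#' [assertCanonicalLayout()] to enforce the full-size geometry
#' (144 tyrosine substrates, or 140 serine/threonine substrates plus 4
#' controls).
#'
#' @slot chipType `"PTK"` or `"STK"`.
#' @slot peptides data.frame with columns `protein`, `start`, `end`, `raw`,
#'   `is_control`; one row per spotted peptide, unique `raw` identifiers.
#'
#' @seealso [makeChipLayout()], [parsePeptideId()]
#' @export
setClass("ChipLayout",
  representation(chipType = "character", peptides = "data.frame"))

setValidity("ChipLayout", function(object) {
  msg <- character()
  if (length(object@chipType) != 1L || !object@chipType %in% .CHIP_TYPES)
    msg <- c(msg, "chipType must be one of \"PTK\", \"STK\"")
  pep <- object@peptides
  if (!all(.PEPTIDE_COLS %in% names(pep)))
    msg <- c(msg, sprintf("peptides must have columns %s",
                          paste(.PEPTIDE_COLS, collapse = ", ")))
  else if (anyDuplicated(pep$raw))
    msg <- c(msg, "peptide identifiers must be unique within a layout")
  if (length(msg)) msg else TRUE
})

#' PhosphoExperiment: peptide x sample phosphorylation signals
#'
#' Container for one chip type's quantified phosphorylation data, extending
#' `SummarizedExperiment`. Assays (peptides as rows, samples as columns):
#' \describe{
#'   \item{`log2`}{normalized log2 signal: exposure-integrated signal,
#'     log2-transformed and centered per peptide within run date.}
#'   \item{`raw_log2`}{log2 signal before date centering.}
#'   \item{`r2`}{per-spot coefficient of determination of the
#'     intensity-vs-exposure fit (quality measure).}
#' }
#' Row metadata carries the parsed peptide identity plus `qc_pass`; column
#' metadata carries `group` (`ET`/`UT`), `run_date`, `chip_id`,
#' `array_position`, `qc_pass`, `qc_reason`, `median_r2`. Object-level
#' metadata stores `chipType`, the signal floor `epsilon` and a `provenance`
#' log of the transforms applied.
#'
#' @seealso [phosphoExperiment()], [dateCenter()], [peptideDeltas()]
#' @export
setClass("PhosphoExperiment", contains = "SummarizedExperiment")

setValidity("PhosphoExperiment", function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$chipType) || !md$chipType %in% .CHIP_TYPES)
    msg <- c(msg, "metadata(x)$chipType must be \"PTK\" or \"STK\"")
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay \"log2\" is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("is_control", "qc_pass") %in% names(rd)))
    msg <- c(msg, "rowData must contain is_control and qc_pass")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "run_date", "qc_pass") %in% names(cd)))
    msg <- c(msg, "colData must contain group, run_date and qc_pass")
  else if (!all(cd$group %in% c("ET", "UT")))
    msg <- c(msg, "group labels must be ET or UT")
  if (length(msg)) msg else TRUE
})

#' DeltaProfile: per-peptide two-group contrast
#'
#' Holds, for every scoring peptide (quality-passing substrate peptide), the
#' contrast of group means of normalized log2 signal (trained minus
#' untrained), together with the chip-wide normalizing constant
#' `max(abs(delta))` used to scale the median kinase statistic into
#' \eqn{[-1, 1]}.
#'
#' @slot delta named numeric vector of per-peptide contrasts.
#' @slot normalizer numeric scalar, `max(abs(delta))` (0 when all deltas are
#'   exactly zero; the kinase statistic is then defined as 0).
#'
#' @seealso [peptideDeltas()], [kinaseStatistic()]
#' @export
setClass("DeltaProfile",
  representation(delta = "numeric", normalizer = "numeric"))

setValidity("DeltaProfile", function(object) {
  msg <- character()
  if (is.null(names(object@delta)) || anyDuplicated(names(object@delta)))
    msg <- c(msg, "delta must be named with unique peptide identifiers")
  if (length(object@normalizer) != 1L || object@normalizer < 0)
    msg <- c(msg, "normalizer must be a single non-negative number")
  if (any(!is.finite(object@delta)))
    msg <- c(msg, "delta values must be finite")
  if (length(msg)) msg else TRUE
})

#' SubstrateMap: rank-weighted kinase to substrate-peptide evidence
#'
#' Maps each kinase to its candidate substrate peptides with the best
#' available evidence rank: rank 0 for in vitro/in vivo (iviv) established
#' relations, ranks 1-12 for in-silico predictions (lower is stronger).
#' Peptides are restricted to the quality-passing substrate peptides of the
#' experiment the map was built against, so substrate sets drawn from the map
#' are always scoreable.
#'
#' @slot chipType `"PTK"` or `"STK"`.
#' @slot evidence data.frame with columns `kinase`, `peptide`, `source`,
#'   `rank`; unique (kinase, peptide) pairs.
#'
#' @seealso [buildSubstrateMap()], [substrateSet()], [validCutoffs()]
#' @export
setClass("SubstrateMap",
  representation(chipType = "character", evidence = "data.frame"))

setValidity("SubstrateMap", function(object) {
  msg <- character()
  ev <- object@evidence
  need <- c("kinase", "peptide", "source", "rank")
  if (!all(need %in% names(ev)))
    msg <- c(msg, sprintf("evidence must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(ev[c("kinase", "peptide")]))
      msg <- c(msg, "evidence must be deduplicated to one row per (kinase, peptide)")
    if (any(ev$rank < 0L | ev$rank > 12L))
      msg <- c(msg, "evidence ranks must lie in 0..12")
    bad <- (ev$source == "iviv" & ev$rank != 0L) |
           (ev$source == "insilico" & ev$rank == 0L)
    if (any(bad))
      msg <- c(msg, "iviv evidence must have rank 0; in-silico evidence rank 1..12")
  }
  if (length(object@chipType) != 1L || !object@chipType %in% .CHIP_TYPES)
    msg <- c(msg, "chipType must be \"PTK\" or \"STK\"")
  if (length(msg)) msg else TRUE
})

#' KinaseScoreSet: ranked upstream-kinase activity scores
#'
#' Result container of [scoreKinases()]. The score table holds, per kinase,
#' the medians over the evidence-rank cutoff scan of the normalized median
#' kinase statistic (`s`), the permutation significance score (`Qsg`), the
#' random-set specificity score (`Qsp`) and the final score
#' (`Q = Qsg + Qsp`), plus the relevance flag (`Qsp > 1.3`). The trace holds
#' the individual per-cutoff analyses behind those medians (the points of a
#' median final score plot).
#'
#' @slot scores data.frame, one row per scored kinase, ordered by `Q`
#'   descending (ties: `Qsp` descending, then kinase name).
#' @slot trace data.frame, one row per (kinase, valid cutoff).
#' @slot unscored character vector of kinases with no cutoff admitting a
#'   substrate set of the minimum size.
#' @slot params named list of scoring parameters (grid, minimum set size,
#'   resampling sizes K and B, seed, sidedness, relevance threshold).
#'
#' @seealso [scoreKinases()], [rankKinases()], [exportKinmapAnnotation()]
#' @export
setClass("KinaseScoreSet",
  representation(scores = "data.frame", trace = "data.frame",
                 unscored = "character", params = "list"))

setValidity("KinaseScoreSet", function(object) {
  msg <- character()
  need <- c("kinase", "s", "Qsg", "Qsp", "Q", "n_peptides_median", "relevant")
  if (!all(need %in% names(object@scores)))
    msg <- c(msg, sprintf("scores must have columns %s",
                          paste(need, collapse = ", ")))
  needt <- c("kinase", "cutoff", "set_size", "s_t", "Qsg_t", "Qsp_t", "Q_t")
  if (!all(needt %in% names(object@trace)))
    msg <- c(msg, sprintf("trace must have columns %s",
                          paste(needt, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
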