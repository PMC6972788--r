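#' @include AllClasses.R
NULL

#' Chip type of an object
#'
#' Returns the peptide-array chip type, `"PTK"` (tyrosine kinase substrates)
#' or `"STK"` (serine/threonine kinase substrates).
#'
#' @param x a [ChipLayout], [PhosphoExperiment] or [SubstrateMap].
#' @return A character scalar, `"PTK"` or `"STK"`.
#' @export
setGeneric("chipType", function(x) standardGeneric("chipType"))

#' Provenance log of applied transforms
#'
#' @param x a [PhosphoExperiment].
#' @return Character vector of transform descriptions, in application order.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Peptide table of a layout or experiment
#'
#' @param x a [ChipLayout] or [PhosphoExperiment].
#' @return A data.frame with columns `protein`, `start`, `end`, `raw`,
#'   `is_control` (one row per spotted peptide).
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' Kinase-substrate evidence of a SubstrateMap
#'
#' @param x a [SubstrateMap].
#' @return data.frame with columns `kinase`, `peptide`, `source`, `rank`
#'   (best rank per pair after deduplication).
#' @export
setGeneric("evidenceTable", function(x) standardGeneric("evidenceTable"))

#' Kinase names covered by a SubstrateMap
#'
#' @param x a [SubstrateMap] or [KinaseScoreSet].
#' @return Character vector of kinase names.
#' @export
setGeneric("kinases", function(x) standardGeneric("kinases"))

#' Ranked per-kinase score table
#'
#' @param x a [KinaseScoreSet].
#' @return data.frame with one row per scored kinase: `kinase`, `s`, `Qsg`,
#'   `Qsp`, `Q`, `n_peptides_median`, `relevant`, ordered by final score.
#' @export
setGeneric("kinaseScores", function(x) standardGeneric("kinaseScores"))

#' Per-cutoff score trace
#'
#' One row per (kinase, admitted evidence-rank cutoff): the individual
#' analysis points summarised by the median final score.
#'
#' @param x a [KinaseScoreSet].
#' @return data.frame with columns `kinase`, `cutoff`, `set_size`, `s_t`,
#'   `Qsg_t`, `Qsp_t`, `Q_t`.
#' @export
setGeneric("cutoffTrace", function(x) standardGeneric("cutoffTrace"))

#' Scoring parameters used to produce a KinaseScoreSet
#'
#' @param x a [KinaseScoreSet].
#' @return Named list of resampling and thresholding parameters.
#' @export
setGeneric("scoreParams", function(x) standardGeneric("scoreParams"))

#' Per-peptide group contrasts of a DeltaProfile
#'
#' @param x a [DeltaProfile].
#' @return Named numeric vector of per-peptide contrasts (trained minus
#'   untrained group mean of normalized log2 signal).
#' @export
setGeneric("deltas", function(x) standardGeneric("deltas"))

#' Normalizing constant of a DeltaProfile
#'
#' @param x a [DeltaProfile].
#' @return Numeric scalar: the maximum absolute per-peptide contrast over the
#'   scoring peptide universe (0 when all contrasts vanish).
#' @export
setGeneric("normalizer", function(x) standardGeneric("normalizer"))
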