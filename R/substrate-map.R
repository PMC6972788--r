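#' Build a rank-weighted substrate map against an experiment
#'
#' Restricts a kinase-substrate evidence table to the scoring peptide
#' universe of an experiment (quality-passing substrate peptides) and
#' deduplicates to the best rank per (kinase, peptide). Kinases left with no
#' peptides are dropped from the map.
#'
#' @param evidence evidence data.frame (see [readEvidenceTable()]).
#' @param pe a [PhosphoExperiment], or a character vector naming the peptide
#'   universe directly.
#' @param chipType chip type tag when `pe` is a plain peptide vector.
#' @return a [SubstrateMap].
#' @export
buildSubstrateMap <- function(evidence, pe, chipType = NULL) {
  if (is(pe, "PhosphoExperiment")) {
    universe <- scoringPeptides(pe)
    chipType <- chipType(pe)
  } else {
    universe <- pe
    if (is.null(chipType))
      stop("chipType is required when passing a peptide vector", call. = FALSE)
  }
  validateEvidence(evidence)
  ev <- dedupEvidence(evidence)
  ev <- ev[ev$peptide %in% universe, , drop = FALSE]
  rownames(ev) <- NULL
  new("SubstrateMap", chipType = chipType, evidence = ev)
}

#' Substrate peptide set of a kinase at an evidence-rank cutoff
#'
#' Peptides whose best evidence rank is at most `cutoff`. In vitro/in vivo
#' (iviv) evidence has rank 0 and is therefore included at every cutoff;
#' raising the cutoff admits progressively weaker in-silico predictions, so
#' sets are nested along the cutoff scan.
#'
#' @param map a [SubstrateMap].
#' @param kinase kinase name.
#' @param cutoff integer in 0..12.
#' @return character vector of peptide identifiers.
#' @export
substrateSet <- function(map, kinase, cutoff) {
  stopifnot(is(map, "SubstrateMap"), cutoff >= 0, cutoff <= 12)
  ev <- evidenceTable(map)
  if (!kinase %in% ev$kinase)
    stop(sprintf("unknown kinase: %s", sQuote(kinase)), call. = FALSE)
  ev$peptide[ev$kinase == kinase & ev$rank <= cutoff]
}

#' Valid cutoffs of the rank scan for one kinase
#'
#' A cutoff is valid when the kinase's substrate set at that cutoff reaches
#' the minimum size `minSize`; each valid cutoff later yields one analysis
#' point of the final-score scan. An empty result marks the kinase
#' unscorable.
#'
#' @param map a [SubstrateMap].
#' @param kinase kinase name.
#' @param cutoffs increasing integer grid (default `0:12`, the iviv-only
#'   point plus the full in-silico rank range).
#' @param minSize minimum substrate set size (default 3; a median over fewer
#'   peptides is degenerate).
#' @return data.frame with columns `cutoff` and `size`, possibly empty.
#' @export
validCutoffs <- function(map, kinase, cutoffs = 0:12, minSize = 3) {
  stopifnot(all(diff(cutoffs) > 0), minSize >= 1)
  sizes <- vapply(cutoffs,
                  function(ct) length(substrateSet(map, kinase, ct)),
                  integer(1))
  keep <- sizes >= minSize
  data.frame(cutoff = as.integer(cutoffs[keep]), size = sizes[keep])
}
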