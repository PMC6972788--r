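#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ChipLayout chip type accessor
#' @param x a `ChipLayout`
#' @export
setMethod("chipType", "ChipLayout", function(x) x@chipType)

#' @describeIn ChipLayout peptide table accessor
#' @export
setMethod("peptides", "ChipLayout", function(x) x@peptides)

#' @describeIn PhosphoExperiment chip type accessor
#' @param x a `PhosphoExperiment`
#' @export
setMethod("chipType", "PhosphoExperiment",
          function(x) metadata(x)$chipType)

#' @describeIn PhosphoExperiment provenance log accessor
#' @export
setMethod("provenance", "PhosphoExperiment",
          function(x) metadata(x)$provenance)

#' @describeIn PhosphoExperiment peptide table (from row metadata)
#' @export
setMethod("peptides", "PhosphoExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  as.data.frame(rd[, intersect(.PEPTIDE_COLS, names(rd)), drop = FALSE])
})

#' @describeIn SubstrateMap chip type accessor
#' @param x a `SubstrateMap`
#' @export
setMethod("chipType", "SubstrateMap", function(x) x@chipType)

#' @describeIn SubstrateMap deduplicated evidence table accessor
#' @export
setMethod("evidenceTable", "SubstrateMap", function(x) x@evidence)

#' @describeIn SubstrateMap kinases present in the map
#' @export
setMethod("kinases", "SubstrateMap",
          function(x) sort(unique(x@evidence$kinase)))

#' @describeIn DeltaProfile per-peptide contrast accessor
#' @param x a `DeltaProfile`
#' @export
setMethod("deltas", "DeltaProfile", function(x) x@delta)

#' @describeIn DeltaProfile normalizing constant accessor
#' @export
setMethod("normalizer", "DeltaProfile", function(x) x@normalizer)

#' @describeIn KinaseScoreSet ranked score table accessor
#' @param x a `KinaseScoreSet`
#' @export
setMethod("kinaseScores", "KinaseScoreSet", function(x) x@scores)

#' @describeIn KinaseScoreSet per-cutoff trace accessor
#' @export
setMethod("cutoffTrace", "KinaseScoreSet", function(x) x@trace)

#' @describeIn KinaseScoreSet scoring parameter accessor
#' @export
setMethod("scoreParams", "KinaseScoreSet", function(x) x@params)

#' @describeIn KinaseScoreSet scored kinases, in ranking order
#' @export
setMethod("kinases", "KinaseScoreSet", function(x) x@scores$kinase)

setMethod("show", "ChipLayout", function(object) {
  pep <- object@peptides
  cat(sprintf("ChipLayout (%s): %d substrate peptide(s), %d control(s)\n",
              object@chipType, sum(!pep$is_control), sum(pep$is_control)))
})

setMethod("show", "PhosphoExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("PhosphoExperiment (%s chip): %d peptides x %d samples\n",
              chipType(object), nrow(object), ncol(object)))
  cat(sprintf("  groups: ET=%d, UT=%d | samples passing QC: %d\n",
              sum(cd$group == "ET"), sum(cd$group == "UT"), sum(cd$qc_pass)))
  cat(sprintf("  scoring peptides (QC pass, non-control): %d\n",
              sum(rd$qc_pass & !rd$is_control)))
  cat(sprintf("  assays: %s\n",
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
  prov <- provenance(object)
  if (length(prov))
    cat("  provenance:", paste(prov, collapse = " -> "), "\n")
})

setMethod("show", "DeltaProfile", function(object) {
  cat(sprintf("DeltaProfile: %d peptides, normalizer = %.4g\n",
              length(object@delta), object@normalizer))
})

setMethod("show", "SubstrateMap", function(object) {
  ev <- object@evidence
  cat(sprintf("SubstrateMap (%s): %d kinases, %d evidence pairs (%d iviv)\n",
              object@chipType, length(unique(ev$kinase)), nrow(ev),
              sum(ev$rank == 0L)))
})

setMethod("show", "KinaseScoreSet", function(object) {
  sc <- object@scores
  cat(sprintf("KinaseScoreSet: %d scored kinase(s), %d relevant (Qsp > %.2f)\n",
              nrow(sc), sum(sc$relevant), object@params$relevanceThreshold))
  if (length(object@unscored))
    cat(sprintf("  unscorable (substrate sets too small): %s\n",
                paste(object@unscored, collapse = ", ")))
  if (nrow(sc)) {
    cat("  top of ranking:\n")
    print(utils::head(sc[, c("kinase", "Q", "Qsp", "s", "relevant")], 5L),
          row.names = FALSE)
  }
})
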