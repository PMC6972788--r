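## Readers and writers for all tabular interchange formats. Input tables may
## be tab-, comma- or semicolon-separated and may use either the decimal
## point or the decimal comma (the dialect of printed European score tables);
## all output uses tabs and decimal points.

#' Read a spot-level intensity table
#'
#' Expected columns: `sample`, `peptide`, `cycle`, `exposure`, `intensity`.
#' One row per quantified spot at one camera exposure of the end-level read.
#'
#' @param path file path (TSV/CSV, header required).
#' @param layout a [ChipLayout]; every peptide in the file must be on it.
#' @return data.frame of spot readings ordered by sample, with numeric
#'   `cycle`, `exposure` (ms) and `intensity` (arbitrary fluorescence units).
#' @export
readSpotTable <- function(path, layout) {
  stopifnot(is(layout, "ChipLayout"))
  df <- .readTable(path, required = c("sample", "peptide", "cycle",
                                      "exposure", "intensity"))
  df$cycle <- .parseNumber(df$cycle, "cycle")
  df$exposure <- .parseNumber(df$exposure, "exposure")
  df$intensity <- .parseNumber(df$intensity, "intensity")
  if (any(!is.finite(df$intensity)))
    stop(sprintf("%s: non-finite intensity in row(s) %s", path,
                 paste(which(!is.finite(df$intensity)), collapse = ", ")),
         call. = FALSE)
  if (any(df$exposure <= 0))
    stop(sprintf("%s: exposure must be positive (row(s) %s)", path,
                 paste(which(df$exposure <= 0), collapse = ", ")), call. = FALSE)
  unknown <- !(df$peptide %in% peptides(layout)$raw)
  if (any(unknown)) {
    bad <- df$peptide[unknown]
    stop(sprintf("%s: peptide(s) not on the %s layout: %s (row(s) %s)",
                 path, chipType(layout),
                 paste(sQuote(unique(bad)), collapse = ", "),
                 paste(utils::head(which(unknown), 10L), collapse = ", ")),
         call. = FALSE)
  }
  df[order(df$sample), c("sample", "peptide", "cycle", "exposure", "intensity")]
}

#' Write a spot-level intensity table
#'
#' @param path output file path (TSV).
#' @param spots data.frame with columns `sample`, `peptide`, `cycle`,
#'   `exposure`, `intensity`.
#' @param header optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
writeSpotTable <- function(path, spots, header = NULL) {
  .assertColumns(spots, c("sample", "peptide", "cycle", "exposure",
                          "intensity"), "spot table")
  .writeTable(spots, path, header = header)
  invisible(path)
}

#' Read a kinase-substrate evidence table
#'
#' Expected columns: `kinase`, `peptide`, `source` (`iviv` for in vitro/in
#' vivo established relations, `insilico` for predicted ones), `rank`
#' (0 for iviv, 1-12 for in-silico predictions, lower = stronger evidence).
#' Duplicate (kinase, peptide) pairs are deduplicated keeping the best
#' (lowest) rank.
#'
#' @param path file path.
#' @return data.frame of evidence records, one row per (kinase, peptide).
#' @export
readEvidenceTable <- function(path) {
  df <- .readTable(path, required = c("kinase", "peptide", "source", "rank"))
  df$rank <- .parseNumber(df$rank, "rank")
  validateEvidence(df, context = path)
  dedupEvidence(df)
}

#' Validate evidence source/rank consistency
#'
#' @param evidence data.frame with columns `kinase`, `peptide`, `source`,
#'   `rank`.
#' @param context label used in error messages (e.g. a file path).
#' @return `TRUE`, invisibly.
#' @export
validateEvidence <- function(evidence, context = "evidence") {
  if (any(!evidence$source %in% c("iviv", "insilico")))
    stop(sprintf("%s: source must be 'iviv' or 'insilico' (row(s) %s)", context,
                 paste(which(!evidence$source %in% c("iviv", "insilico")),
                       collapse = ", ")), call. = FALSE)
  bad <- evidence$rank != as.integer(evidence$rank) |
    evidence$rank < 0 | evidence$rank > 12
  if (any(bad))
    stop(sprintf("%s: rank must be an integer in 0..12 (row(s) %s)", context,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  bad <- (evidence$source == "iviv" & evidence$rank != 0) |
    (evidence$source == "insilico" & evidence$rank == 0)
  if (any(bad))
    stop(sprintf(
      "%s: iviv evidence must have rank 0 and in-silico evidence rank 1..12 (row(s) %s)",
      context, paste(which(bad), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Deduplicate evidence keeping the best rank per (kinase, peptide)
#'
#' @param evidence validated evidence data.frame.
#' @return data.frame with unique (kinase, peptide) pairs; a pair's rank
#'   never increases through deduplication.
#' @export
dedupEvidence <- function(evidence) {
  evidence$rank <- as.integer(evidence$rank)
  o <- order(evidence$kinase, evidence$peptide, evidence$rank)
  evidence <- evidence[o, , drop = FALSE]
  keep <- !duplicated(evidence[c("kinase", "peptide")])
  out <- evidence[keep, c("kinase", "peptide", "source", "rank"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an evidence table
#'
#' @param path output file path (TSV).
#' @param evidence data.frame of evidence records.
#' @param header optional comment lines.
#' @export
writeEvidenceTable <- function(path, evidence, header = NULL) {
  .assertColumns(evidence, c("kinase", "peptide", "source", "rank"),
                 "evidence table")
  .writeTable(evidence, path, header = header)
  invisible(path)
}

#' Read sample metadata
#'
#' Expected columns: `sample_id`, `group` (`ET` endurance-trained /
#' `UT` untrained), `run_date`; optional `chip_id`, `array_position`,
#' `excluded` (logical), `exclude_reason`. A sample marked excluded must
#' carry a non-empty reason.
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
readSampleMeta <- function(path) {
  df <- .readTable(path, required = c("sample_id", "group", "run_date"))
  if (anyDuplicated(df$sample_id))
    stop(sprintf("%s: duplicate sample_id(s): %s", path,
                 paste(sQuote(unique(df$sample_id[duplicated(df$sample_id)])),
                       collapse = ", ")), call. = FALSE)
  if (any(!df$group %in% c("ET", "UT")))
    stop(sprintf("%s: unknown group label(s): %s", path,
                 paste(sQuote(unique(df$group[!df$group %in% c("ET", "UT")])),
                       collapse = ", ")), call. = FALSE)
  if (is.null(df$excluded)) df$excluded <- FALSE
  else df$excluded <- as.logical(df$excluded)
  if (is.null(df$exclude_reason)) df$exclude_reason <- ""
  if (any(df$excluded & !nzchar(df$exclude_reason)))
    stop(sprintf("%s: excluded sample(s) without a reason: %s", path,
                 paste(sQuote(df$sample_id[df$excluded &
                                           !nzchar(df$exclude_reason)]),
                       collapse = ", ")), call. = FALSE)
  if (!is.null(df$array_position))
    df$array_position <- as.integer(.parseNumber(df$array_position,
                                                 "array_position"))
  df
}

#' Write sample metadata
#'
#' @param path output file path (TSV).
#' @param meta metadata data.frame.
#' @param header optional comment lines.
#' @export
writeSampleMeta <- function(path, meta, header = NULL) {
  .assertColumns(meta, c("sample_id", "group", "run_date"), "sample metadata")
  .writeTable(meta, path, header = header)
  invisible(path)
}

#' Write a ranked kinase score table
#'
#' Columns: `kinase`, `s`, `Qsg`, `Qsp`, `Q`, `n_peptides_median`,
#' `relevant`. Rows are ordered by final score `Q` descending (ties by
#' specificity score, then kinase name); output always uses the decimal
#' point.
#'
#' @param path output file path (TSV).
#' @param scores a [KinaseScoreSet] or a score data.frame.
#' @param header optional comment lines.
#' @export
writeKinaseScores <- function(path, scores, header = NULL) {
  if (is(scores, "KinaseScoreSet")) scores <- kinaseScores(scores)
  .assertColumns(scores, c("kinase", "s", "Qsg", "Qsp", "Q",
                           "n_peptides_median", "relevant"), "score table")
  scores <- rankKinases(scores)
  .writeTable(scores, path, header = header)
  invisible(path)
}

#' Read a kinase score table
#'
#' Reads score tables written by [writeKinaseScores()] as well as transcribed
#' published summary tables in the decimal-comma dialect (semicolon
#' separated, e.g. `3,80` for 3.80). Only columns present in the file are
#' returned; every column except `kinase` and `relevant` is parsed
#' numerically.
#'
#' @param path file path.
#' @return data.frame with a `kinase` column and numeric score columns.
#' @export
readKinaseScores <- function(path) {
  df <- .readTable(path, required = "kinase")
  for (col in setdiff(names(df), c("kinase", "relevant")))
    df[[col]] <- .parseNumber(df[[col]], col)
  if (!is.null(df$relevant)) df$relevant <- as.logical(df$relevant)
  df
}

#' Read an intensity matrix written by writeIntensityMatrix
#'
#' @param path file path (TSV; peptides as rows, samples as columns).
#' @return numeric matrix with peptide rownames and sample colnames.
#' @export
readIntensityMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write a peptide x sample matrix
#'
#' @param path output file path (TSV).
#' @param m numeric matrix with peptide rownames and sample colnames.
#' @param header optional comment lines.
#' @export
writeIntensityMatrix <- function(path, m, header = NULL) {
  df <- data.frame(peptide = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTable(df, path, header = header)
  invisible(path)
}
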