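## Pipeline stages and presentation exports. The four stages
## (simulate / preprocess / score / report) read and write only the tabular
## interchange formats, are idempotent, and stamp every output file with the
## package version, the seed and a config fingerprint, so identical configs
## produce identical bytes.

.runHeader <- function(config) {
  c(sprintf("ukaKinome %s",
            as.character(utils::packageVersion("ukaKinome"))),
    sprintf("seed=%s", config$seed %||% "NA"),
    sprintf("config=%s", .configHash(config)))
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with top-level keys: `out_dir`; `chip_type`; optional
#' `simulate` (fields of [simConfig()]); optional `preprocess`
#' (`epsilon`, `qc_k`, `qc_r_min`, `qc_f`); optional `score`
#' (`min_size`, `k_random_sets`, `b_permutations`, `alternative`,
#' `exact_threshold`, `relevance_threshold`, `cutoff_max`); optional
#' `paths` (`spots`, `meta`, `evidence`, `layout`) for data not produced by
#' the simulate stage; and `seed`.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as parsed from YAML).
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir))
    stop("config field 'out_dir' is required", call. = FALSE)
  cfg$chip_type <- cfg$chip_type %||% "PTK"
  if (!cfg$chip_type %in% .CHIP_TYPES)
    stop(sprintf("config field 'chip_type' must be PTK or STK, got %s",
                 sQuote(cfg$chip_type)), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  for (p in cfg$paths)
    if (!file.exists(p))
      stop(sprintf("configured input path does not exist: %s", p),
           call. = FALSE)
  cfg
}

.stagePaths <- function(cfg) {
  d <- cfg$out_dir
  list(spots = cfg$paths$spots %||% file.path(d, "spots.tsv"),
       meta = cfg$paths$meta %||% file.path(d, "meta.tsv"),
       evidence = cfg$paths$evidence %||% file.path(d, "evidence.tsv"),
       layout = cfg$paths$layout %||% file.path(d, "layout.tsv"),
       matrix = file.path(d, "matrix.tsv"),
       rawMatrix = file.path(d, "raw_log2.tsv"),
       qcSamples = file.path(d, "qc_samples.tsv"),
       qcPeptides = file.path(d, "qc_peptides.tsv"),
       scores = file.path(d, "scores.tsv"),
       trace = file.path(d, "trace.tsv"),
       kinmap = file.path(d, "kinmap_annotation.tsv"),
       plotPoints = file.path(d, "plot_points.tsv"),
       groupMeans = file.path(d, "group_means.tsv"),
       provenance = file.path(d, "provenance.txt"))
}

#' Run the simulate stage
#'
#' Generates a synthetic experiment from the `simulate` section of the run
#' config and writes its tables into `out_dir`.
#'
#' @param cfg run config (see [readRunConfig()]).
#' @return invisible list of written paths.
#' @export
runSimulate <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  simArgs <- cfg$simulate %||% list()
  simArgs$chipType <- cfg$chip_type
  simArgs$seed <- simArgs$seed %||% cfg$seed
  if (!is.null(simArgs$planted)) simArgs$planted <- unlist(simArgs$planted)
  sim <- simulateExperiment(do.call(simConfig, simArgs))
  writeSimulation(sim, cfg$out_dir, header = .runHeader(cfg))
  invisible(.stagePaths(cfg))
}

#' Run the preprocess stage
#'
#' Reads spot readings, metadata and layout, assembles a
#' [PhosphoExperiment] and writes the centered matrix, the raw log2 matrix
#' and the QC reports.
#'
#' @param cfg run config.
#' @return the [PhosphoExperiment], invisibly.
#' @export
runPreprocess <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  p <- .stagePaths(cfg)
  for (need in c("spots", "meta", "layout"))
    if (!file.exists(p[[need]]))
      stop(sprintf("preprocess stage: missing upstream input %s", p[[need]]),
           call. = FALSE)
  layout <- readLayoutTable(p$layout, chipType = cfg$chip_type)
  spots <- readSpotTable(p$spots, layout)
  meta <- readSampleMeta(p$meta)
  pp <- cfg$preprocess %||% list()
  pe <- phosphoExperiment(spots, meta, layout,
                          epsilon = pp$epsilon %||% 1,
                          qcK = pp$qc_k %||% 3,
                          qcRMin = pp$qc_r_min %||% 0.5,
                          qcF = pp$qc_f %||% 0.5)
  hdr <- .runHeader(cfg)
  writeIntensityMatrix(p$matrix, SummarizedExperiment::assay(pe, "log2"),
                       header = hdr)
  writeIntensityMatrix(p$rawMatrix,
                       SummarizedExperiment::assay(pe, "raw_log2"),
                       header = hdr)
  cd <- as.data.frame(SummarizedExperiment::colData(pe))
  .writeTable(cd[c("sample_id", "group", "run_date", "qc_pass", "qc_reason",
                   "median_r2")], p$qcSamples, header = hdr)
  rd <- as.data.frame(SummarizedExperiment::rowData(pe))
  .writeTable(rd[c("raw", "is_control", "qc_pass")], p$qcPeptides,
              header = hdr)
  writeLines(c(paste0("# ", hdr), provenance(pe)), p$provenance)
  invisible(pe)
}

## Rebuild a PhosphoExperiment from the preprocess stage's files.
.readStageExperiment <- function(cfg) {
  p <- .stagePaths(cfg)
  for (need in c("matrix", "rawMatrix", "qcSamples", "qcPeptides"))
    if (!file.exists(p[[need]]))
      stop(sprintf("score stage: missing preprocess output %s", p[[need]]),
           call. = FALSE)
  centered <- readIntensityMatrix(p$matrix)
  rawLog2 <- readIntensityMatrix(p$rawMatrix)
  sq <- .readTable(p$qcSamples,
                   required = c("sample_id", "group", "run_date", "qc_pass"))
  rq <- .readTable(p$qcPeptides, required = c("raw", "is_control", "qc_pass"))
  pepTab <- parsePeptideId(rq$raw,
                           controls = rq$raw[as.logical(rq$is_control)])
  rd <- S4Vectors::DataFrame(pepTab, qc_pass = as.logical(rq$qc_pass),
                             row.names = rq$raw)
  cd <- S4Vectors::DataFrame(
    sample_id = sq$sample_id, group = sq$group, run_date = sq$run_date,
    qc_pass = as.logical(sq$qc_pass),
    qc_reason = sq$qc_reason %||% "",
    median_r2 = if (is.null(sq$median_r2)) NA_real_ else
      .parseNumber(sq$median_r2, "median_r2"),
    row.names = sq$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = centered[rq$raw, sq$sample_id, drop = FALSE],
                  raw_log2 = rawLog2[rq$raw, sq$sample_id, drop = FALSE]),
    rowData = rd, colData = cd,
    metadata = list(chipType = cfg$chip_type, epsilon = 1,
                    provenance = "restored from preprocess stage files"))
  new("PhosphoExperiment", se)
}

#' Run the score stage
#'
#' Restores the preprocessed experiment, builds the substrate map from the
#' evidence table and writes the ranked score table and the per-cutoff
#' trace.
#'
#' @param cfg run config.
#' @return the [KinaseScoreSet], invisibly.
#' @export
runScore <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  p <- .stagePaths(cfg)
  pe <- .readStageExperiment(cfg)
  if (!file.exists(p$evidence))
    stop(sprintf("score stage: missing evidence table %s", p$evidence),
         call. = FALSE)
  map <- buildSubstrateMap(readEvidenceTable(p$evidence), pe)
  sc <- cfg$score %||% list()
  scores <- scoreKinases(
    pe, map,
    cutoffs = 0:(sc$cutoff_max %||% 12),
    minSize = sc$min_size %||% 3,
    K = sc$k_random_sets %||% 999,
    B = sc$b_permutations %||% 999,
    seed = cfg$seed,
    alternative = sc$alternative %||% "two.sided",
    exactThreshold = sc$exact_threshold %||% 20000,
    relevanceThreshold = sc$relevance_threshold %||% 1.3)
  hdr <- .runHeader(cfg)
  writeKinaseScores(p$scores, scores, header = hdr)
  .writeTable(cutoffTrace(scores), p$trace, header = hdr)
  invisible(scores)
}

#' Run the report stage
#'
#' Writes the presentation artifacts: kinome-tree annotation table,
#' final-score plot points and the per-group mean heatmap matrix.
#'
#' @param cfg run config.
#' @return invisible list of written paths.
#' @export
runReport <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  p <- .stagePaths(cfg)
  if (!file.exists(p$scores))
    stop(sprintf("report stage: missing score output %s", p$scores),
         call. = FALSE)
  scores <- readKinaseScores(p$scores)
  trace <- .readTable(p$trace)
  for (col in setdiff(names(trace), "kinase"))
    trace[[col]] <- .parseNumber(trace[[col]], col)
  pe <- .readStageExperiment(cfg)
  hdr <- .runHeader(cfg)
  .writeTable(exportKinmapAnnotation(scores), p$kinmap, header = hdr)
  .writeTable(exportPlotData(trace), p$plotPoints, header = hdr)
  writeIntensityMatrix(p$groupMeans, groupMeanMatrix(pe), header = hdr)
  invisible(p)
}

#' Run all pipeline stages in order
#'
#' @param cfg run config; must contain a `simulate` section (or `paths`
#'   pointing at existing data).
#' @return invisible list of output paths.
#' @export
runAll <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  if (!is.null(cfg$simulate)) runSimulate(cfg)
  runPreprocess(cfg)
  runScore(cfg)
  runReport(cfg)
}

#' Kinome-tree annotation export
#'
#' One row per kinase, formatted for phylogenetic kinome-tree web tools:
#' node size is the specificity score clipped to \eqn{[0, 2]} (2 = most
#' specific) and node color is the normalized kinase statistic clipped to
#' \eqn{[-1, +1]} (negative = less active in the trained group).
#'
#' @param scores a [KinaseScoreSet] or score data.frame with columns
#'   `kinase`, `Qsp`, `s`.
#' @return data.frame with columns `kinase`, `size`, `color`.
#' @export
exportKinmapAnnotation <- function(scores) {
  if (is(scores, "KinaseScoreSet")) scores <- kinaseScores(scores)
  data.frame(kinase = scores$kinase,
             size = .clip(scores$Qsp, 0, 2),
             color = .clip(scores$s, -1, 1),
             stringsAsFactors = FALSE)
}

#' Final-score plot point table
#'
#' The data behind a median final score plot: one point per (kinase, valid
#' cutoff) with the final score, the statistic, the specificity score and
#' the substrate set size (plot dot size).
#'
#' @param trace per-cutoff trace (from [cutoffTrace()]) or a
#'   [KinaseScoreSet].
#' @return data.frame with columns `kinase`, `cutoff`, `set_size`, `s_t`,
#'   `Qsp_t`, `Q_t`.
#' @export
exportPlotData <- function(trace) {
  if (is(trace, "KinaseScoreSet")) trace <- cutoffTrace(trace)
  trace[, c("kinase", "cutoff", "set_size", "s_t", "Qsp_t", "Q_t")]
}
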