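## Upstream kinase activity scoring. Per kinase and evidence-rank cutoff the
## pipeline computes
##   s_t   normalized median kinase statistic: median per-peptide group
##         contrast over the substrate set, scaled by the chip-wide maximum
##         absolute contrast so that s_t lies in [-1, 1];
##   Qsp_t specificity score: -log10 of the probability that a uniformly
##         drawn random peptide set of the same size yields a statistic as
##         extreme as the observed one;
##   Qsg_t significance score: -log10 of the group-label permutation p-value
##         of |s_t| (the statistic, including its normalizer, is recomputed
##         under every relabelling);
##   Q_t = Qsg_t + Qsp_t, the final score.
## The reported per-kinase values are medians over the valid cutoffs of the
## rank scan, and ranking is by median final score Q.

.TIE_TOL <- 1e-12

#' Per-peptide group contrast profile
#'
#' Computes, for every scoring peptide, the contrast of group means of
#' normalized log2 signal (ET minus UT over quality-passing samples);
#' positive values mean higher phosphorylation in the endurance-trained
#' group. The chip-wide maximum absolute contrast is stored as the
#' normalizer of the kinase statistic.
#'
#' @param pe a [PhosphoExperiment] with at least 2 included samples per
#'   group.
#' @return a [DeltaProfile].
#' @export
peptideDeltas <- function(pe) {
  ctx <- .scoringContext(pe)
  new("DeltaProfile", delta = ctx$delta, normalizer = ctx$normalizer)
}

## Shared per-experiment scoring state: signal matrix over the scoring
## universe and included samples, group labels, observed contrasts.
.scoringContext <- function(pe) {
  stopifnot(is(pe, "PhosphoExperiment"))
  cd <- SummarizedExperiment::colData(pe)
  keep <- cd$qc_pass
  group <- cd$group[keep]
  if (sum(group == "ET") < 2L || sum(group == "UT") < 2L)
    stop("each group needs at least 2 included samples", call. = FALSE)
  X <- SummarizedExperiment::assay(pe, "log2")[scoringPeptides(pe), keep,
                                               drop = FALSE]
  delta <- .groupDelta(X, group)
  list(X = X, group = group, delta = delta,
       normalizer = max(abs(delta), 0))
}

.groupDelta <- function(X, group) {
  rowMeans(X[, group == "ET", drop = FALSE]) -
    rowMeans(X[, group == "UT", drop = FALSE])
}

#' Normalized median kinase statistic
#'
#' Median of the per-peptide group contrasts over a substrate peptide set,
#' divided by the chip-wide maximum absolute contrast, so the statistic lies
#' in \eqn{[-1, 1]}. When every contrast on the chip is exactly zero the
#' statistic is defined as 0.
#'
#' @param profile a [DeltaProfile].
#' @param peptides character vector of substrate peptide identifiers.
#' @return numeric scalar in \eqn{[-1, 1]}.
#' @export
kinaseStatistic <- function(profile, peptides) {
  stopifnot(is(profile, "DeltaProfile"))
  if (length(peptides) == 0L)
    stop("empty substrate peptide set", call. = FALSE)
  d <- deltas(profile)
  miss <- setdiff(peptides, names(d))
  if (length(miss))
    stop(sprintf("peptide(s) outside the scoring universe: %s",
                 paste(sQuote(miss), collapse = ", ")), call. = FALSE)
  if (profile@normalizer == 0) return(0)
  stats::median(d[peptides]) / profile@normalizer
}

#' Random-peptide-set specificity score
#'
#' Draws `K` uniform random peptide subsets (without replacement, of the
#' observed set size) from the scoring universe, recomputes the normalized
#' median statistic for each, and reports
#' `Qsp = -log10((r + 1) / (K + 1))` where `r` counts random sets at least
#' as extreme as the observed statistic. With `alternative = "two.sided"`
#' (default) extremeness is `|s_rand| >= |s_obs|`; `"directional"` counts
#' only excursions in the observed sign's direction.
#'
#' @param profile a [DeltaProfile].
#' @param setSize observed substrate set size.
#' @param sObs observed normalized median kinase statistic.
#' @param K number of random sets (default 999).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param alternative `"two.sided"` or `"directional"`.
#' @return list with elements `Qsp`, `r`, `K`, `p`.
#' @export
specificityScore <- function(profile, setSize, sObs, K = 999, seed = NULL,
                             alternative = c("two.sided", "directional")) {
  stopifnot(is(profile, "DeltaProfile"), K >= 1)
  alternative <- match.arg(alternative)
  d <- deltas(profile)
  if (setSize > length(d))
    stop("set size exceeds the scoring peptide universe", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  meds <- cpp_random_set_medians(unname(d), as.integer(setSize),
                                 as.integer(K))
  sRand <- if (profile@normalizer > 0) meds / profile@normalizer else
    rep(0, K)
  r <- .countExtreme(sRand, sObs, alternative)
  p <- (r + 1) / (K + 1)
  list(Qsp = -log10(p), r = r, K = as.integer(K), p = p)
}

.countExtreme <- function(sRand, sObs, alternative) {
  if (alternative == "two.sided")
    sum(abs(sRand) >= abs(sObs) - .TIE_TOL)
  else if (sObs >= 0)
    sum(sRand >= sObs - .TIE_TOL)
  else
    sum(sRand <= sObs + .TIE_TOL)
}

#' Group-label permutation significance score
#'
#' Permutes the ET/UT sample labels, recomputes the normalized median kinase
#' statistic for the peptide set under every relabelling (contrasts and the
#' chip-wide normalizer included), and reports the two-sided
#' permutation p-value of `|s|` on the -log10 scale. When the number of
#' distinct label assignments `choose(n, nET)` is at most `exactThreshold`
#' all assignments are enumerated and `p = b / B_total` without pseudocount
#' (the observed assignment is among them, so `p >= 1 / B_total`); otherwise
#' `B` random permutations are drawn and `p = (b + 1) / (B + 1)`.
#'
#' @param x a [PhosphoExperiment], or a peptide x sample matrix of
#'   normalized log2 signals (rows = scoring universe).
#' @param peptides substrate peptide identifiers (subset of the rows).
#' @param group per-sample `"ET"`/`"UT"` labels; required when `x` is a
#'   matrix, ignored otherwise.
#' @param B number of sampled permutations (default 999).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param exactThreshold enumerate exactly when `choose(n, nET)` is at most
#'   this (default 20000).
#' @return list with elements `Qsg`, `p`, `b`, `nPerm`, `exact`, `sObs`.
#' @export
significanceScore <- function(x, peptides, group = NULL, B = 999,
                              seed = NULL, exactThreshold = 20000) {
  if (is(x, "PhosphoExperiment")) {
    ctx <- .scoringContext(x)
    X <- ctx$X; group <- ctx$group
  } else {
    X <- x
    if (is.null(group)) stop("group labels are required for matrix input",
                             call. = FALSE)
    if (sum(group == "ET") < 2L || sum(group == "UT") < 2L)
      stop("each group needs at least 2 samples", call. = FALSE)
  }
  idx <- match(peptides, rownames(X))
  if (anyNA(idx))
    stop(sprintf("peptide(s) outside the scoring universe: %s",
                 paste(sQuote(peptides[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- .permutationDeltas(X, group, B, exactThreshold)
  delta <- .groupDelta(X, group)
  norm <- max(abs(delta), 0)
  sObs <- if (norm > 0) stats::median(delta[idx]) / norm else 0
  res <- .permutationPValue(perm, idx, sObs)
  c(list(Qsg = -log10(res$p)), res, list(sObs = sObs))
}

## Recompute per-peptide contrasts under all (or B sampled) relabellings:
## D[, j] = X %*% w_j with w the signed group-mean weights. Returned once
## per kinase and shared across the cutoffs of the rank scan (common random
## numbers; each cutoff's p-value remains marginally valid).
.permutationDeltas <- function(X, group, B, exactThreshold) {
  n <- length(group)
  n1 <- sum(group == "ET"); n2 <- n - n1
  nAssign <- choose(n, n1)
  if (nAssign <= exactThreshold) {
    comb <- utils::combn(n, n1)
    W <- matrix(-1 / n2, n, ncol(comb))
    W[cbind(as.vector(comb), rep(seq_len(ncol(comb)), each = n1))] <- 1 / n1
    exact <- TRUE
  } else {
    w <- ifelse(group == "ET", 1 / n1, -1 / n2)
    W <- vapply(seq_len(B), function(b) w[sample.int(n)], numeric(n))
    exact <- FALSE
  }
  D <- X %*% W
  list(D = D, norms = cpp_col_max_abs(D), exact = exact)
}

.permutationPValue <- function(perm, idx, sObs) {
  meds <- cpp_col_medians(perm$D[idx, , drop = FALSE])
  sStar <- ifelse(perm$norms > 0, meds / perm$norms, 0)
  b <- sum(abs(sStar) >= abs(sObs) - .TIE_TOL)
  nPerm <- ncol(perm$D)
  p <- if (perm$exact) b / nPerm else (b + 1) / (nPerm + 1)
  list(p = p, b = b, nPerm = nPerm, exact = perm$exact)
}

#' Score one kinase across the evidence-rank cutoff scan
#'
#' For each valid cutoff (substrate set of at least `minSize` peptides)
#' computes the statistic triplet and the final score
#' `Q_t = Qsg_t + Qsp_t`; the kinase-level values are the medians over valid
#' cutoffs, and the kinase is flagged relevant when its median specificity
#' score exceeds `relevanceThreshold` (1.3, i.e. p < 0.05). Resampling uses
#' a substream derived deterministically from `(seed, kinase)`, so results
#' do not depend on the order in which kinases are scored.
#'
#' @param pe a [PhosphoExperiment].
#' @param map a [SubstrateMap] built against `pe`.
#' @param kinase kinase name.
#' @inheritParams scoreKinases
#' @return list with elements `score` (one-row data.frame) and `trace`
#'   (per-cutoff data.frame), or `NULL` when the kinase is unscorable.
#' @export
scoreKinase <- function(pe, map, kinase, cutoffs = 0:12, minSize = 3,
                        K = 999, B = 999, seed = 1,
                        alternative = c("two.sided", "directional"),
                        exactThreshold = 20000, relevanceThreshold = 1.3) {
  alternative <- match.arg(alternative)
  ctx <- .scoringContext(pe)
  .scoreKinaseCtx(ctx, map, kinase, cutoffs, minSize, K, B, seed,
                  alternative, exactThreshold, relevanceThreshold)
}

.scoreKinaseCtx <- function(ctx, map, kinase, cutoffs, minSize, K, B, seed,
                            alternative, exactThreshold, relevanceThreshold) {
  vc <- validCutoffs(map, kinase, cutoffs = cutoffs, minSize = minSize)
  if (nrow(vc) == 0L) return(NULL)
  if (!is.null(seed)) set.seed(.deriveSeed(seed, kinase))
  perm <- .permutationDeltas(ctx$X, ctx$group, B, exactThreshold)
  profile <- new("DeltaProfile", delta = ctx$delta,
                 normalizer = ctx$normalizer)
  tr <- lapply(seq_len(nrow(vc)), function(i) {
    set <- substrateSet(map, kinase, vc$cutoff[i])
    idx <- match(set, rownames(ctx$X))
    sT <- if (ctx$normalizer > 0)
      stats::median(ctx$delta[idx]) / ctx$normalizer else 0
    qsg <- -log10(.permutationPValue(perm, idx, sT)$p)
    qsp <- specificityScore(profile, length(set), sT, K = K, seed = NULL,
                            alternative = alternative)$Qsp
    data.frame(kinase = kinase, cutoff = vc$cutoff[i], set_size = vc$size[i],
               s_t = sT, Qsg_t = qsg, Qsp_t = qsp, Q_t = qsg + qsp,
               stringsAsFactors = FALSE)
  })
  trace <- do.call(rbind, tr)
  medQsp <- stats::median(trace$Qsp_t)
  score <- data.frame(
    kinase = kinase,
    s = stats::median(trace$s_t),
    Qsg = stats::median(trace$Qsg_t),
    Qsp = medQsp,
    Q = stats::median(trace$Q_t),
    n_peptides_median = as.integer(stats::median(trace$set_size)),
    relevant = medQsp > relevanceThreshold,
    stringsAsFactors = FALSE)
  list(score = score, trace = trace)
}

#' Score all kinases of a substrate map
#'
#' Runs the full upstream kinase analysis: for every kinase in the map, the
#' evidence-rank cutoff scan with per-cutoff statistic, specificity and
#' significance scores, summarised by medians and ranked by median final
#' score.
#'
#' @param pe a [PhosphoExperiment].
#' @param map a [SubstrateMap] built against `pe`.
#' @param kinaseNames kinases to score (default: all in the map).
#' @param cutoffs increasing integer cutoff grid (default `0:12`).
#' @param minSize minimum substrate set size per cutoff (default 3).
#' @param K random peptide sets per cutoff for the specificity score
#'   (default 999).
#' @param B sampled label permutations for the significance score (default
#'   999; exact enumeration replaces sampling for small cohorts, see
#'   `exactThreshold`).
#' @param seed base integer seed; per-kinase substreams are derived from
#'   `(seed, kinase)`. `NULL` uses the current RNG stream (order-dependent).
#' @param alternative sidedness of the specificity score (default
#'   `"two.sided"`).
#' @param exactThreshold enumerate label assignments exactly when
#'   `choose(n, nET)` is at most this (default 20000).
#' @param relevanceThreshold specificity threshold for the relevance flag
#'   (default 1.3, i.e. p < 0.05).
#' @return a [KinaseScoreSet].
#' @export
scoreKinases <- function(pe, map, kinaseNames = NULL, cutoffs = 0:12,
                         minSize = 3, K = 999, B = 999, seed = 1,
                         alternative = c("two.sided", "directional"),
                         exactThreshold = 20000, relevanceThreshold = 1.3) {
  alternative <- match.arg(alternative)
  stopifnot(is(map, "SubstrateMap"))
  ctx <- .scoringContext(pe)
  kinaseNames <- sort(kinaseNames %||% kinases(map))
  res <- lapply(kinaseNames, function(k)
    .scoreKinaseCtx(ctx, map, k, cutoffs, minSize, K, B, seed,
                    alternative, exactThreshold, relevanceThreshold))
  names(res) <- kinaseNames
  ok <- !vapply(res, is.null, logical(1))
  scores <- do.call(rbind, lapply(res[ok], `[[`, "score"))
  trace <- do.call(rbind, lapply(res[ok], `[[`, "trace"))
  if (is.null(scores))
    scores <- data.frame(kinase = character(), s = numeric(),
                         Qsg = numeric(), Qsp = numeric(), Q = numeric(),
                         n_peptides_median = integer(), relevant = logical())
  if (is.null(trace))
    trace <- data.frame(kinase = character(), cutoff = integer(),
                        set_size = integer(), s_t = numeric(),
                        Qsg_t = numeric(), Qsp_t = numeric(), Q_t = numeric())
  scores <- rankKinases(scores)
  rownames(trace) <- NULL
  new("KinaseScoreSet", scores = scores, trace = trace,
      unscored = kinaseNames[!ok],
      params = list(cutoffs = cutoffs, minSize = minSize, K = K, B = B,
                    seed = seed, alternative = alternative,
                    exactThreshold = exactThreshold,
                    relevanceThreshold = relevanceThreshold))
}

#' Rank a kinase score table
#'
#' Orders by median final score `Q` descending; ties are broken by
#' specificity score `Qsp` descending, then by kinase name, so output order
#' is deterministic.
#'
#' @param scores a score data.frame (columns `kinase`, `Q`, `Qsp`, ...) or a
#'   [KinaseScoreSet].
#' @return the ranked data.frame.
#' @export
rankKinases <- function(scores) {
  if (is(scores, "KinaseScoreSet")) scores <- kinaseScores(scores)
  out <- scores[order(-scores$Q, -scores$Qsp, scores$kinase), , drop = FALSE]
  rownames(out) <- NULL
  out
}
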