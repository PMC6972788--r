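---
title: "Upstream kinase activity inference: model, scores and design choices"
author: "ukaKinome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upstream kinase activity inference: model, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ukaKinome)
```

# The inference problem

Peptide microarray kinome profiling measures, per sample, the
phosphorylation signal a cell lysate deposits on a fixed panel of 15-mer
substrate peptides (144 tyrosine-kinase substrates on a PTK chip; 140
serine/threonine substrates plus 4 positive controls on an STK chip). The
quantity of scientific interest is one level up: which *kinases* differ in
activity between two groups of donors — here endurance-trained (ET) versus
untrained (UT) subjects. A kinase is never observed directly; it is
represented by the set of peptides annotated as its substrates, with
annotation quality encoded as an evidence rank (0 = in vitro/in vivo
established, "iviv"; 1–12 = in-silico prediction, lower is stronger).

The pipeline turns spot-level fluorescence into a per-kinase score triplet
and a ranking, in four stages.

# Preprocessing

**Exposure integration.** At the end-level read cycle each spot is imaged
at several camera exposures (10, 20, 50, 100, 200 ms). Fluorescence is
assumed linear in exposure time within this range; per peptide we fit
ordinary least squares with intercept and report

\[ \text{signal} = \hat\beta_1 \times 100\,\text{ms}, \]

a "100 ms equivalent" in arbitrary fluorescence units (AU). The fit's
R² doubles as a spot quality measure: saturated or blank spots show no
exposure response (R² is defined as 0 when the intensity variance is zero;
non-positive slopes floor at \(\varepsilon\)). The multi-exposure design is
exactly what makes this robust — a single exposure cannot distinguish a
bright artifact from genuine kinase activity.

**Floor and log transform.** Signals below \(\varepsilon = 1\) AU
(configurable) are set to \(\varepsilon\) before log2, so the floor maps to
0 and the log is always defined.

**Quality control.** Samples fail when (a) their median log2 signal over
substrate peptides falls more than \(k = 3\) MADs below the cohort level —
the signature of insufficient antibody binding — or (b) their median
exposure-fit R² drops below \(r_{\min} = 0.5\) (detection failure). When
run dates are known, rule (a) compares each sample against its *own run
date's* median level: day-to-day batch offsets shift entire dates
coherently and are removed later by centering, whereas antibody failure is
a per-sample event; comparing against the global cohort can otherwise
disqualify a whole (perfectly usable) batch that merely ran dim. With
fewer than 3 assessable samples QC is skipped with a warning. Peptides
pass when their raw signal exceeds \(\varepsilon\) in at least half
(\(f = 0.5\)) of the included samples; control peptides never enter
scoring.

**Date centering.** Per peptide and per run date, the mean over that
date's included samples is subtracted. This removes additive batch offsets
on the log scale while preserving the between-group contrast as long as
the ET fraction is (approximately) constant across dates — which is why
the synthetic generator stratifies groups across dates, and why a real
study should do the same. Centering is idempotent and excluded samples are
left untouched. An open question in the upstream tooling is whether
centering is per peptide within date or per sample; per-peptide-within-date
is implemented because it is the variant that removes peptide-specific
batch response while leaving each sample's relative peptide pattern intact.

# Scoring

Let \(\delta_p\) be the ET-minus-UT difference of group means of
normalized log2 signal for scoring peptide \(p\) (quality-passing,
non-control), and let \(S(t)\) be a kinase's substrate set at evidence-rank
cutoff \(t\) (peptides with best rank \(\le t\); iviv peptides are in every
set). Only cutoffs with \(|S(t)| \ge m\) (default \(m = 3\); a median over
fewer peptides is degenerate) are analysed.

**Normalized median kinase statistic.**

\[ s_t = \frac{\operatorname{median}_{p \in S(t)} \delta_p}
             {\max_p |\delta_p|} \in [-1, 1]. \]

The normalizer is the chip-wide maximum absolute contrast, which matches
the \([-1, +1]\) color scale of kinome-tree exports. When every
\(\delta_p\) is exactly zero, \(s_t := 0\). The upstream tooling never
defines its normalization; this choice is the simplest one that produces
the documented range and makes \(|s| = 1\) attainable ("the set moved as
much as the most-moved peptide on the chip").

**Specificity score.** \(K\) random peptide sets of size \(|S(t)|\) are
drawn uniformly without replacement from the scoring universe and their
statistics recomputed;

\[ Q_{sp,t} = -\log_{10}\frac{r + 1}{K + 1}, \]

with \(r\) the number of random sets at least as extreme as the observed
statistic. Extremeness is two-sided by default
(\(|s_{\text{rand}}| \ge |s_{\text{obs}}|\)). A one-sided variant counting
only excursions in the observed sign's direction is available
(`alternative = "directional"`), but it is *not* the default for a
calibration reason: because the direction is chosen after seeing the data,
the directional p-value is doubly optimistic under a sign-symmetric null
(\(P(p \le \alpha) = 2\alpha\)), so the conventional relevance reading of
\(Q_{sp} > 1.3\) as "\(p < 0.05\)" would actually operate near a 10%
false-flag rate. The two-sided default keeps the flag calibrated, which
the test suite verifies empirically on null simulations.

**Significance score.** The ET/UT labels are permuted and the *entire*
statistic — contrasts, normalizer, set median — recomputed per
relabelling:

\[ Q_{sg,t} = -\log_{10} p_{\text{perm}}, \qquad
   p_{\text{perm}} = P\left(|s^\ast| \ge |s_{\text{obs}}|\right). \]

When \(\binom{n}{n_{ET}} \le 20{,}000\) all label assignments are
enumerated and \(p = b/B_{\text{total}}\) without pseudocount (the observed
assignment is among them, so \(p \ge 1/B_{\text{total}}\)); otherwise
\(B\) permutations are sampled and the add-one estimator
\((b+1)/(B+1)\) is used. The upstream tooling names the significance score
but never defines its construction; a two-sided label-permutation test is
the natural nonparametric choice, and the \(-\log_{10}\) scale is forced
by the final score's additive definition.

**Final score and ranking.** \(Q_t = Q_{sg,t} + Q_{sp,t}\) holds exactly
per cutoff. The kinase-level report takes medians over valid cutoffs —
median \(s\), median \(Q_{sg}\), median \(Q_{sp}\), and the median of
\(Q_t\) itself (so the reported \(Q\) need not equal the sum of the
reported medians; both conventions are plausible, the median of the
per-cutoff sum is reported because it summarises the quantity actually
ranked per analysis point, and the separate medians are emitted alongside).
Kinases are ranked by \(Q\) descending with ties broken by \(Q_{sp}\)
descending, then name — fully deterministic output. A kinase whose sets
never reach \(m\) is reported as unscorable rather than silently dropped.
Relevance is flagged at \(Q_{sp} > 1.3\) (\(\approx p < 0.05\)); no
multiple-testing correction is applied, deliberately mirroring the
upstream practice — users screening many kinases should treat the flag as
a screening threshold, not a family-wise guarantee.

**Determinism.** Each kinase's resampling uses a substream seeded from a
hash of (seed, kinase name), so results are independent of scoring order;
permutation draws are made once per kinase and shared across its cutoffs
(common random numbers — each cutoff's p-value remains marginally valid,
and the nested sets make the shared draws an efficiency win, not a bias).
Tie comparisons use a \(10^{-12}\) tolerance so that exact ties (e.g. the
identity permutation) count as extreme regardless of floating-point
representation.

# The synthetic data generator

`simulateExperiment()` emulates the statistical structure the analysis
assumes; its defaults are the study conditions the pipeline targets:
\(n_{ET} = 12\) vs \(n_{UT} = 13\), the canonical chip geometries, three
run dates with groups stratified evenly, exposures 10–200 ms.

On the log2 scale: peptide baseline \(b_p \sim N(8, 1)\) (about 256 AU —
comfortably above the 1 AU floor, as real quality-passing peptides are),
one batch offset per run date \(\sim N(0, 0.5)\), residual spot noise
\(\sim N(0, 0.5)\), and planted per-kinase effects transmitted to a
rank-\(r\) substrate as \(e \cdot 0.85^{r}\) — weaker in-silico evidence
transmits less signal, giving the cutoff scan genuine structure. Raw
fluorescence at exposure \(t\) is \((2^{x_{ps}}/100) \cdot t\) times 1%
multiplicative measurement noise; "failed" samples are attenuated tenfold,
which is what the sample QC is built to catch. Noise levels are one-time
choices: 0.5 log2 units of spot noise makes a 1.0 log2-unit planted effect
a clear but not trivial recovery target at these sample sizes, and 0.5
units of date offset is large enough that skipping the centering step
visibly corrupts contrasts.

What the generator does **not** emulate: spot spatial autocorrelation,
washing artifacts, per-cycle kinetics (only end-level reads are modelled;
kinetic velocity analysis is out of scope), heavy-tailed or correlated
peptide noise, and real kinase–substrate biology (evidence maps are random
unless supplied). Passing tests therefore demonstrate that the *machinery*
is correct and calibrated under the assumed model — not that the model
captures every property of real chips.

`makeToyFixture()` is a deterministic miniature (24 peptides, 4 + 4
samples, one up-, one down-, one null kinase) whose permutation null
(\(\binom{8}{4} = 70\)) and random-set null (\(\binom{24}{4}\) subsets) are
exhaustively enumerable. The universe is larger than the minimal
12-peptide sketch one might first reach for: with mirrored 4-up/4-down
planted sets, a tiny universe leaves random sets too likely to hit planted
peptides, capping the achievable specificity below the 1.3 relevance
threshold; 16 unaffected peptides give the planted kinases an exact
two-sided random-set p around 0.015, safely beyond it. The null kinase's
substrates sit on unaffected peptides only, so its scores are genuinely
null.

# Numerical and interface choices

- Signal floor \(\varepsilon = 1\) AU; with log2 this maps the floor to 0.
- Input tables accept decimal commas (printed European tables) and
  semicolon/tab/comma separators; all output uses tabs and decimal points.
- Peptide identifiers follow `PROTEIN_START_END` (1-based inclusive);
  identifiers whose span is not 15 residues are accepted with a warning by
  default because printed chip identifiers sometimes span fewer (strict
  mode rejects them); control peptides are whitelisted by name.
- Evidence deduplication keeps the best (lowest) rank per (kinase,
  peptide) — a peptide's rank never increases.
- Resampling defaults \(K = B = 999\); exact enumeration threshold 20,000
  assignments.
- Pipeline stage outputs carry version, seed and a config fingerprint in
  their headers and contain no timestamps, so identical configs produce
  identical bytes.

The test suite works at deliberately modest problem sizes — the 24-peptide
fixture for enumeration-backed checks, 144-peptide simulated studies
(10 null datasets → 200 null kinase scores for flag calibration; 100
seeded runs for planted-effect recovery) — sizes chosen so the full suite
documents the pipeline's statistical behaviour in minutes while the
enumeration oracles stay exact.

# Limitations

- The commercial analysis tool this pipeline parallels is proprietary;
  its exact normalization and significance constructions are undocumented,
  so numeric agreement with its outputs is not a goal — the package's
  constructions are stated above and isolated behind interfaces
  (`alternative`, `exactThreshold`, the normalizer inside
  `kinaseStatistic()`) so alternatives can be swapped.
- Whether in-silico peptides should enter sets cumulatively by rank
  threshold (implemented) or be re-weighted per rank is unknown upstream;
  the cutoff scan makes the choice visible rather than hiding it.
- No kinome-wide error control across kinases; the relevance flag is
  per-kinase.
- Evidence tables must be supplied by the user for real data; the bundled
  generator's maps are synthetic.

# A complete run

```{r example, eval = FALSE}
sim <- simulateExperiment(simConfig(planted = c(KIN05 = 1.0), seed = 1))
pe  <- phosphoExperiment(sim$spots, sim$meta, sim$layout)
map <- buildSubstrateMap(sim$evidence, pe)
res <- scoreKinases(pe, map, seed = 1)
kinaseScores(res)          # ranked table: s, Qsg, Qsp, Q, relevance
cutoffTrace(res)           # per-cutoff points (median final score plot data)
exportKinmapAnnotation(res)  # kinome-tree node sizes and colors
```
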