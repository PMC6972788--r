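#' Parse peptide spot identifiers
#'
#' Array spot identifiers follow the grammar `PROTEIN_START_END`: a
#' gene/protein symbol followed by the first and last residue (1-based,
#' inclusive) of the spotted peptide representing a putative phosphorylation
#' site, e.g. `"ZAP70_485_497"`. Spotted substrate peptides are 15-mers, but
#' identifiers as printed on commercial chips sometimes span fewer residues
#' (e.g. `"VGFR2_1168_1180"` spans 13); by default such identifiers are
#' accepted with a warning, while `strict = TRUE` rejects them. Identifiers
#' listed in `controls` (positive-control peptides with free-form names) skip
#' the grammar entirely.
#'
#' @param raw character vector of spot identifiers.
#' @param controls character vector of whitelisted control-peptide
#'   identifiers.
#' @param strict logical; if `TRUE`, substrate identifiers whose residue span
#'   is not exactly 15 are an error instead of a warning.
#' @return data.frame with one row per identifier and columns `protein`,
#'   `start`, `end`, `raw`, `is_control`. For control peptides `protein` is
#'   the raw name and `start`/`end` are `NA`.
#' @examples
#' parsePeptideId(c("ZAP70_485_497", "FGFR2_761_773"))
#' @export
parsePeptideId <- function(raw, controls = character(), strict = FALSE) {
  if (length(raw) == 0L || any(!nzchar(raw)))
    stop("peptide identifiers must be non-empty", call. = FALSE)
  is_control <- raw %in% controls
  protein <- ifelse(is_control, raw, NA_character_)
  start <- end <- rep(NA_integer_, length(raw))

  sub <- which(!is_control)
  if (length(sub)) {
    m <- regmatches(raw[sub], regexec("^(.+)_([0-9]+)_([0-9]+)$", raw[sub]))
    bad <- lengths(m) != 4L
    if (any(bad))
      stop(sprintf(
        "malformed peptide identifier(s): %s (expected PROTEIN_START_END)",
        paste(sQuote(raw[sub][bad]), collapse = ", ")), call. = FALSE)
    protein[sub] <- vapply(m, `[`, "", 2L)
    start[sub] <- as.integer(vapply(m, `[`, "", 3L))
    end[sub] <- as.integer(vapply(m, `[`, "", 4L))
    if (any(start[sub] < 1L))
      stop(sprintf("peptide identifier(s) with start residue < 1: %s",
                   paste(sQuote(raw[sub][start[sub] < 1L]), collapse = ", ")),
           call. = FALSE)
    if (any(start[sub] > end[sub]))
      stop(sprintf("peptide identifier(s) with start > end: %s",
                   paste(sQuote(raw[sub][start[sub] > end[sub]]),
                         collapse = ", ")), call. = FALSE)
    span <- end[sub] - start[sub] + 1L
    off <- span != 15L
    if (any(off)) {
      what <- paste(sQuote(raw[sub][off]), collapse = ", ")
      if (strict)
        stop(sprintf("substrate peptide(s) not spanning 15 residues: %s", what),
             call. = FALSE)
      warning(sprintf(
        "substrate peptide(s) not spanning 15 residues (accepted leniently): %s",
        what), call. = FALSE)
    }
  }
  data.frame(protein = protein, start = start, end = end, raw = raw,
             is_control = is_control, stringsAsFactors = FALSE)
}

#' Format peptide identities back to spot identifiers
#'
#' Inverse of [parsePeptideId()]: substrate peptides are rendered as
#' `PROTEIN_START_END`, control peptides keep their raw name. For
#' identifiers that conform to the grammar this round-trips exactly.
#'
#' @param pep data.frame as returned by [parsePeptideId()].
#' @return character vector of identifiers.
#' @export
formatPeptideId <- function(pep) {
  ifelse(pep$is_control, pep$raw,
         sprintf("%s_%d_%d", pep$protein, pep$start, pep$end))
}

#' Construct a chip layout
#'
#' @param ids character vector of spot identifiers (substrates and controls).
#' @param chipType `"PTK"` or `"STK"`.
#' @param controls identifiers within `ids` that are positive-control
#'   peptides.
#' @param strict passed to [parsePeptideId()].
#' @return a [ChipLayout].
#' @export
makeChipLayout <- function(ids, chipType = c("PTK", "STK"),
                           controls = character(), strict = FALSE) {
  chipType <- match.arg(chipType)
  new("ChipLayout", chipType = chipType,
      peptides = parsePeptideId(ids, controls = controls, strict = strict))
}

#' Assert the canonical production geometry of a layout
#'
#' Production tyrosine-kinase chips spot 144 substrate peptides and no
#' controls; serine/threonine chips spot 140 substrate peptides plus 4
#' positive-control peptides. Miniature layouts (simulation, tests) fail
#' this assertion by design.
#'
#' @param layout a [ChipLayout].
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
assertCanonicalLayout <- function(layout) {
  stopifnot(is(layout, "ChipLayout"))
  want <- .CANONICAL_LAYOUT[[chipType(layout)]]
  pep <- peptides(layout)
  got <- c(substrates = sum(!pep$is_control), controls = sum(pep$is_control))
  if (!identical(unname(got), unname(want)))
    stop(sprintf(
      "%s layout has %d substrate / %d control peptides; canonical geometry is %d / %d",
      chipType(layout), got[["substrates"]], got[["controls"]],
      want[["substrates"]], want[["controls"]]), call. = FALSE)
  invisible(TRUE)
}
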