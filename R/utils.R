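## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Parse numbers written with either a decimal point or a decimal comma
## (European table dialect). Thousands separators are not supported.
.parseNumber <- function(x, what = "value") {
  x <- trimws(as.character(x))
  x <- gsub(",", ".", x, fixed = TRUE)
  ## unicode minus occasionally survives transcription of printed tables
  x <- gsub("−", "-", x)
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x) & nzchar(x) & x != "NA"
  if (any(bad))
    stop(sprintf("non-numeric %s: %s", what,
                 paste(sQuote(unique(x[bad])), collapse = ", ")), call. = FALSE)
  out
}

## Deterministic 31-bit seed derived from a base seed and a string key, so
## per-kinase resampling substreams do not depend on evaluation order.
.deriveSeed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

.assertColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s) %s",
                 path, paste(sQuote(miss), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

## Field separator sniffing for tabular text: semicolon (decimal-comma
## dialect), tab, then comma.
.sniffSep <- function(path) {
  first <- readLines(path, n = 25L)
  first <- first[!startsWith(first, "#")][1L]
  if (is.na(first)) stop(sprintf("%s: empty file", path), call. = FALSE)
  if (grepl(";", first, fixed = TRUE)) return(";")
  if (grepl("\t", first, fixed = TRUE)) return("\t")
  ","
}

.readTable <- function(path, required = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character", check.names = TRUE,
                          quote = "\"")
  if (!is.null(required)) .assertColumns(df, required, path)
  df
}

## All data files are written as TSV with decimal points, optionally with
## '#'-prefixed header comment lines (version/seed/config provenance).
.writeTable <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, dec = ".")
  invisible(path)
}

## Tiny polynomial string hash (hex) for config fingerprints in output headers.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
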