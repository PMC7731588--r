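# 12-column tabular similarity-hit I/O (the "outfmt 6" dialect):
# qseqid sseqid pident length mismatch gapopen qstart qend sstart send
# evalue bitscore. Extra trailing columns are ignored; fewer are an error.

hit_columns <- c("query", "subject", "pident", "alignment_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

# Every table-reading routine reports the file it opens through this hook so
# per-task I/O contracts can be asserted; see options("orthoflow.file_open_hook").
notify_file_open <- function(path) {
  hook <- getOption("orthoflow.file_open_hook")
  if (is.function(hook)) hook(path)
  invisible(path)
}

#' Read a tabular similarity-hit file
#'
#' Parses the 12-column tab-separated format emitted by protein similarity
#' search tools (`qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`). Comment lines starting with `#` are
#' skipped; an E-value printed as `0.0` parses to exact zero; alignment
#' coordinates are retained verbatim and never interpreted.
#'
#' @param path Path to the hit file.
#' @param query_taxon Optional genome code; when given, every row's query
#'   gene must belong to this genome (error otherwise).
#' @return A tibble with columns `query`, `subject`, `pident`,
#'   `alignment_length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, one row per input row in file order.
#' @examples
#' f <- tempfile()
#' writeLines("eco|b1\tstm|s9\t87.5\t200\t25\t0\t1\t200\t1\t200\t1e-80\t300", f)
#' read_hits(f)
#' @export
read_hits <- function(path, query_taxon = NULL) {
  if (!file.exists(path)) stop("hit file not found: ", path, call. = FALSE)
  notify_file_open(path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- tibble::tibble(
      query = character(), subject = character(), pident = numeric(),
      alignment_length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = numeric(), bitscore = numeric()
    )
    return(out)
  }
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  short <- lengths(fields) < 12L
  if (any(short)) {
    stop("line ", lineno[which(short)[1]], " of ", path, " has ",
         lengths(fields)[which(short)[1]], " fields (12 required)",
         call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- is.na(v) & !is.na(m[, col])
    if (any(bad) || anyNA(m[, col])) {
      i <- which(bad | is.na(m[, col]))[1]
      stop("line ", lineno[i], " of ", path, ": unparseable ", what,
           " field \"", m[i, col], "\"", call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    query = m[, 1], subject = m[, 2],
    pident = num(3, "percent-identity"),
    alignment_length = as.integer(num(4, "alignment-length")),
    mismatch = as.integer(num(5, "mismatch")),
    gapopen = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "E-value"),
    bitscore = num(12, "bit-score")
  )
  if (any(out$evalue < 0)) {
    stop("line ", lineno[which(out$evalue < 0)[1]], " of ", path,
         ": negative E-value", call. = FALSE)
  }
  if (any(out$pident < 0 | out$pident > 100)) {
    stop("line ", lineno[which(out$pident < 0 | out$pident > 100)[1]],
         " of ", path, ": percent identity outside [0, 100]", call. = FALSE)
  }
  if (!is.null(query_taxon)) {
    qt <- gene_taxon(out$query)
    if (any(qt != query_taxon)) {
      stop("hit file ", path, " contains queries from taxon \"",
           qt[qt != query_taxon][1], "\" but taxon \"", query_taxon,
           "\" was expected", call. = FALSE)
    }
  }
  out
}

#' @rdname read_hits
#' @param hits A hit tibble as returned by [read_hits()].
#' @return `write_hits()` returns `path` invisibly. Numeric fields are
#'   serialized with enough digits that reading the file back reproduces the
#'   table exactly.
#' @export
write_hits <- function(hits, path) {
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
    hits$query, hits$subject, num_c17(hits$pident),
    hits$alignment_length, hits$mismatch, hits$gapopen,
    hits$qstart, hits$qend, hits$sstart, hits$send,
    num_c17(hits$evalue), num_c17(hits$bitscore)
  )
  writeLines(lines, path)
  invisible(path)
}

# shortest decimal text that round-trips the double exactly
num_c17 <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- as.numeric(out) != x
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out
}

#' Negative log10 E-value transform
#'
#' The score transform used throughout the pipeline: small E-values become
#' large positive scores. An E-value of exactly 0 (reported by search tools
#' when the true value underflows) maps to `cap`; any finite value is bounded
#' above by `cap`; E-values of 1 or more clamp to 0 so that scores are never
#' negative.
#'
#' @param evalue Non-negative numeric vector of E-values.
#' @param cap Positive cap on the transformed score (default 181).
#' @return Numeric vector in `[0, cap]`, monotone non-increasing in `evalue`.
#' @examples
#' neg_log10_evalue(c(1e-20, 0, 1))
#' @export
neg_log10_evalue <- function(evalue, cap = 181) {
  stopifnot(is.numeric(evalue), is.numeric(cap), cap > 0)
  if (any(evalue < 0, na.rm = TRUE)) {
    stop("negative E-value(s): ", evalue[evalue < 0][1], call. = FALSE)
  }
  out <- ifelse(evalue == 0, cap, pmin(-log10(evalue), cap))
  pmax(out, 0)
}
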