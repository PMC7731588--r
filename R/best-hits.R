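#' Percent match of an alignment
#'
#' Coverage of the shorter of the two sequences by the aligned region:
#' `100 * alignment_length / min(query_length, subject_length)`, capped at
#' 100. Together with the E-value this forms the hit-acceptance filter.
#'
#' @param alignment_length Aligned columns (>= 1), vectorized.
#' @param query_length,subject_length Sequence lengths in residues (>= 1).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @examples
#' percent_match(50, 100, 120)
#' @export
percent_match <- function(alignment_length, query_length, subject_length) {
  stopifnot(all(alignment_length >= 1), all(query_length >= 1),
            all(subject_length >= 1))
  pmin(100, 100 * alignment_length / pmin(query_length, subject_length))
}

#' Hit-acceptance filter
#'
#' A hit is retained iff its E-value is at most `10^evalue_exponent_cutoff`
#' and its percent match is at least `percent_match_cutoff`.
#'
#' @param evalue Numeric vector of E-values.
#' @param pm Numeric vector of percent-match values (see [percent_match()]).
#' @param config A [pipeline_config()].
#' @return Logical vector.
#' @export
passes_filter <- function(evalue, pm, config = pipeline_config()) {
  evalue <= 10^config$evalue_exponent_cutoff &
    pm >= config$percent_match_cutoff
}

#' Best between-genome hits and within-genome self hits for one genome
#'
#' Scans one genome's individual-against-all hit table and produces, per
#' subject genome, the filtered best-hit table: for each query gene, exactly
#' the subject genes whose E-value ties the minimum over that subject genome
#' (ties are compared on the capped -log10 transform, so two E-values of 0
#' tie exactly). Within-genome hits (subject genome equal to the query
#' genome, subject gene different from the query) that pass the filter are
#' all kept — not reduced to best-only — because inparalog detection compares
#' arbitrary within-genome pairs against a per-gene cutoff. A gene's hit to
#' itself is always discarded. Query genes with no passing hit are absent.
#'
#' When several rows report the same (query, subject) gene pair (multiple
#' local alignments), the row with the best E-value represents the pair.
#'
#' @param hits Hit tibble ([read_hits()]) whose queries all belong to `taxon`.
#' @param lengths Named numeric vector of gene lengths covering every gene in
#'   `hits` (see [gene_lengths()]).
#' @param config A [pipeline_config()].
#' @param taxon Query genome code; defaults to the taxon of the first query.
#' @return A list with `between` — a named list of best-hit tibbles keyed by
#'   subject taxon, each with columns `query`, `subject`, `nle` (-log10
#'   E-value), `pm` and attributes `query_taxon`/`subject_taxon` — and
#'   `self` — the within-genome table in the same shape.
#' @export
find_best_hits <- function(hits, lengths, config = pipeline_config(),
                           taxon = NULL) {
  if (nrow(hits) == 0) {
    if (is.null(taxon)) stop("empty hit table and no taxon given",
                             call. = FALSE)
    return(list(between = list(),
                self = empty_best_hit_table(taxon, taxon)))
  }
  qtax <- gene_taxon(hits$query)
  if (is.null(taxon)) taxon <- qtax[1]
  if (any(qtax != taxon)) {
    stop("query gene ", hits$query[qtax != taxon][1],
         " does not belong to genome ", taxon, call. = FALSE)
  }
  h <- hits[hits$query != hits$subject, , drop = FALSE]
  if (nrow(h) == 0) {
    return(list(between = list(),
                self = empty_best_hit_table(taxon, taxon)))
  }
  missing <- setdiff(unique(c(h$query, h$subject)), names(lengths))
  if (length(missing) > 0) {
    stop("unknown gene length for: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  h$pm <- percent_match(h$alignment_length,
                        lengths[h$query], lengths[h$subject])
  h <- h[passes_filter(h$evalue, h$pm, config), , drop = FALSE]
  h$nle <- neg_log10_evalue(h$evalue, config$zero_evalue_cap)
  h$subject_taxon <- gene_taxon(h$subject)

  # one row per (query, subject) gene pair: best E-value, then best pm
  h <- h |>
    dplyr::group_by(.data$query, .data$subject) |>
    dplyr::arrange(dplyr::desc(.data$nle), dplyr::desc(.data$pm),
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  self <- h[h$subject_taxon == taxon,
            c("query", "subject", "nle", "pm"), drop = FALSE]
  self <- sort_best_hits(self)
  attr(self, "query_taxon") <- taxon
  attr(self, "subject_taxon") <- taxon

  between_all <- h[h$subject_taxon != taxon, , drop = FALSE]
  between <- list()
  for (st in radix_sort(unique(between_all$subject_taxon))) {
    b <- between_all[between_all$subject_taxon == st, , drop = FALSE]
    b <- b |>
      dplyr::group_by(.data$query) |>
      dplyr::filter(.data$nle == max(.data$nle)) |>
      dplyr::ungroup()
    b <- sort_best_hits(b[, c("query", "subject", "nle", "pm")])
    attr(b, "query_taxon") <- taxon
    attr(b, "subject_taxon") <- st
    between[[st]] <- b
  }
  list(between = between, self = self)
}

empty_best_hit_table <- function(query_taxon, subject_taxon) {
  out <- tibble::tibble(query = character(), subject = character(),
                        nle = numeric(), pm = numeric())
  attr(out, "query_taxon") <- query_taxon
  attr(out, "subject_taxon") <- subject_taxon
  out
}

sort_best_hits <- function(tbl) {
  tbl[radix_order(tbl$query, tbl$subject), , drop = FALSE]
}

#' Read and write best-hit tables
#'
#' Best-hit tables are stored one file per ordered genome pair (the sparse
#' layout that lets any pairing task load exactly two files): a 4-column TSV
#' `query`, `subject`, `neg_log10_evalue`, `percent_match`, sorted by query
#' then subject so output is byte-reproducible. Scores are serialized with
#' enough digits to round-trip exactly.
#'
#' @param table A best-hit tibble from [find_best_hits()].
#' @param path File path.
#' @return `write_best_hits()` returns `path` invisibly; `read_best_hits()`
#'   returns the table with its taxon attributes restored from the arguments.
#' @export
write_best_hits <- function(table, path) {
  tbl <- sort_best_hits(table)
  lines <- c("query\tsubject\tneg_log10_evalue\tpercent_match",
             sprintf("%s\t%s\t%s\t%s", tbl$query, tbl$subject,
                     num_c17(tbl$nle), num_c17(tbl$pm)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_best_hits
#' @param query_taxon,subject_taxon Genome codes recorded on the returned
#'   table; inferred from the rows when omitted.
#' @export
read_best_hits <- function(path, query_taxon = NULL, subject_taxon = NULL) {
  if (!file.exists(path)) stop("best-hit file not found: ", path,
                               call. = FALSE)
  notify_file_open(path)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] !=
        "query\tsubject\tneg_log10_evalue\tpercent_match") {
    stop("line 1 of ", path, ": missing best-hit header", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- empty_best_hit_table(query_taxon %||% NA_character_,
                                subject_taxon %||% NA_character_)
    return(out)
  }
  fields <- stringr::str_split(body, stringr::fixed("\t"))
  bad <- lengths(fields) != 4L
  if (any(bad)) {
    stop("line ", which(bad)[1] + 1L, " of ", path,
         ": expected 4 tab-separated fields", call. = FALSE)
  }
  m <- t(vapply(fields, identity, character(4)))
  nle <- suppressWarnings(as.numeric(m[, 3]))
  pm <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(nle) || anyNA(pm)) {
    stop("line ", which(is.na(nle) | is.na(pm))[1] + 1L, " of ", path,
         ": unparseable numeric field", call. = FALSE)
  }
  out <- tibble::tibble(query = m[, 1], subject = m[, 2], nle = nle, pm = pm)
  attr(out, "query_taxon") <- query_taxon %||% gene_taxon(out$query)[1]
  attr(out, "subject_taxon") <- subject_taxon %||% gene_taxon(out$subject)[1]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
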