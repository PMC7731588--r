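#' Raw pair score from two directed hit scores
#'
#' The raw weight of a gene pair is the mean of the two directed
#' -log10 E-values: `w = (s_ab + s_ba) / 2`. Symmetric in its arguments and
#' non-negative whenever the inputs are (they are, after capping/clamping).
#'
#' @param nle_ab,nle_ba Non-negative -log10 E-values of the two directions.
#' @return Numeric vector of raw scores.
#' @examples
#' raw_score(20, 30)
#' @export
raw_score <- function(nle_ab, nle_ba) {
  stopifnot(all(nle_ab >= 0), all(nle_ba >= 0))
  (nle_ab + nle_ba) / 2
}

#' Reciprocal best hits between two genomes
#'
#' A pair (x in A, y in B) is an ortholog candidate iff y is among x's best
#' hits in B and x is among y's best hits in A (ties at the best E-value all
#' count). The raw score is [raw_score()] of the two stored -log10 E-values.
#'
#' @param best_ab Best-hit table A -> B ([find_best_hits()] /
#'   [read_best_hits()]).
#' @param best_ba Best-hit table B -> A for the same genome pair.
#' @return Tibble with columns `a` (gene of A), `b` (gene of B), `w`; each
#'   unordered pair appears once, rows sorted. Attributes `taxon_a`,
#'   `taxon_b`.
#' @export
reciprocal_best_pairs <- function(best_ab, best_ba) {
  ta <- attr(best_ab, "query_taxon"); tb <- attr(best_ab, "subject_taxon")
  if (!identical(attr(best_ba, "query_taxon"), tb) ||
      !identical(attr(best_ba, "subject_taxon"), ta)) {
    stop("best-hit tables are not the two orderings of one genome pair: ",
         ta, "->", tb, " vs ", attr(best_ba, "query_taxon"), "->",
         attr(best_ba, "subject_taxon"), call. = FALSE)
  }
  hits_ab <- tibble::tibble(a = best_ab$query, b = best_ab$subject,
                            nle_ab = best_ab$nle)
  hits_ba <- tibble::tibble(b = best_ba$query, a = best_ba$subject,
                            nle_ba = best_ba$nle)
  out <- dplyr::inner_join(hits_ab, hits_ba, by = c("a", "b"))
  out <- tibble::tibble(a = out$a, b = out$b,
                        w = raw_score(out$nle_ab, out$nle_ba))
  out <- out[radix_order(out$a, out$b), , drop = FALSE]
  attr(out, "taxon_a") <- ta
  attr(out, "taxon_b") <- tb
  out
}

#' Normalize ortholog scores within one genome pair
#'
#' Each raw score is divided by the average raw score of all ortholog pairs
#' identified between the two genomes, so that scores are comparable across
#' genome pairs with different overall divergence. By construction the mean
#' normalized score of every genome pair is 1.
#'
#' @param pairs Tibble from [reciprocal_best_pairs()] (columns `a`, `b`, `w`).
#' @return Tibble with columns `a`, `b`, `category` (`"ortholog"`), `w`,
#'   `w_norm`. If all raw scores are zero the normalized scores are defined
#'   as 0 and a warning is raised.
#' @export
normalize_ortholog_scores <- function(pairs) {
  normalize_by_mean(pairs, "ortholog")
}

normalize_by_mean <- function(pairs, category) {
  if (nrow(pairs) == 0) {
    return(tibble::tibble(a = character(), b = character(),
                          category = character(), w = numeric(),
                          w_norm = numeric()))
  }
  m <- mean(pairs$w)
  if (m == 0) {
    warning("all raw ", category, " scores are zero; normalized scores set to 0",
            call. = FALSE)
    w_norm <- rep(0, nrow(pairs))
  } else {
    w_norm <- pairs$w / m
  }
  tibble::tibble(a = pairs$a, b = pairs$b, category = category,
                 w = pairs$w, w_norm = w_norm)
}

#' Per-gene best between-genome score level
#'
#' For each gene of one genome, the maximum -log10 E-value it achieves over
#' its best hits against every other genome. This is the reference level the
#' inparalog rule compares within-genome hits against: a within-genome
#' reciprocal hit counts as inparalogous only if each direction scores at
#' least as well as the query gene's best between-genome hit. Genes with no
#' passing between-genome hit are absent.
#'
#' @param best_tables List of best-hit tables for one query genome against
#'   every other genome (possibly empty).
#' @return Named numeric vector, gene identifier to cutoff.
#' @export
inter_genome_cutoffs <- function(best_tables) {
  if (length(best_tables) == 0) return(stats::setNames(numeric(), character()))
  all <- dplyr::bind_rows(lapply(best_tables,
                                 function(t) t[, c("query", "nle")]))
  if (nrow(all) == 0) return(stats::setNames(numeric(), character()))
  agg <- all |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(cutoff = max(.data$nle), .groups = "drop")
  stats::setNames(agg$cutoff, agg$query)
}

#' Within-genome inparalog pairs
#'
#' An unordered within-genome pair (x, y) is inparalogous iff passing hits
#' exist in both directions and each direction's -log10 E-value is at least
#' the query gene's best between-genome level ([inter_genome_cutoffs()]);
#' ties qualify. Genes with no between-genome hit get cutoff 0, so
#' genome-private duplicate families are still detected. The raw score is
#' [raw_score()] of the two directions.
#'
#' @param self_table Within-genome table from [find_best_hits()] (all
#'   passing self-genome hits, both directions possibly present).
#' @param cutoffs Named vector from [inter_genome_cutoffs()].
#' @return Tibble with columns `a`, `b` (a < b), `w`, sorted.
#' @export
find_inparalogs <- function(self_table, cutoffs) {
  if (nrow(self_table) == 0) {
    return(tibble::tibble(a = character(), b = character(), w = numeric()))
  }
  cut_of <- function(g) {
    v <- unname(cutoffs[g])
    v[is.na(v)] <- 0
    v
  }
  fwd <- self_table[self_table$nle >= cut_of(self_table$query), , drop = FALSE]
  # join each surviving directed hit with its reverse
  rev <- tibble::tibble(query = fwd$subject, subject = fwd$query,
                        nle_rev = fwd$nle)
  both <- dplyr::inner_join(
    tibble::tibble(query = fwd$query, subject = fwd$subject, nle = fwd$nle),
    rev, by = c("query", "subject")
  )
  if (nrow(both) == 0) {
    return(tibble::tibble(a = character(), b = character(), w = numeric()))
  }
  a <- pmin(both$query, both$subject)
  b <- pmax(both$query, both$subject)
  out <- tibble::tibble(a = a, b = b, w = raw_score(both$nle, both$nle_rev))
  out <- dplyr::distinct(out)
  out <- out[radix_order(out$a, out$b), , drop = FALSE]
  out
}

#' Normalize inparalog scores for one genome
#'
#' The normalization constant is the average raw score over the genome's
#' inparalog pairs in which at least one member has an ortholog in another
#' genome (set `config$inparalog_norm_both` to require both members). If no
#' pair qualifies, the constant falls back to the mean over all of the
#' genome's inparalog pairs.
#'
#' @param pairs Tibble from [find_inparalogs()] (columns `a`, `b`, `w`).
#' @param ortholog_genes Character vector of genes of this genome that have
#'   at least one ortholog.
#' @param config A [pipeline_config()].
#' @return Tibble with columns `a`, `b`, `category` (`"inparalog"`), `w`,
#'   `w_norm`.
#' @export
normalize_inparalog_scores <- function(pairs, ortholog_genes,
                                       config = pipeline_config()) {
  if (nrow(pairs) == 0) {
    return(normalize_by_mean(pairs, "inparalog"))
  }
  in_og_a <- pairs$a %in% ortholog_genes
  in_og_b <- pairs$b %in% ortholog_genes
  qualifies <- if (config$inparalog_norm_both) in_og_a & in_og_b
               else in_og_a | in_og_b
  m <- if (any(qualifies)) mean(pairs$w[qualifies]) else mean(pairs$w)
  if (m == 0) {
    warning("all raw inparalog scores are zero; normalized scores set to 0",
            call. = FALSE)
    w_norm <- rep(0, nrow(pairs))
  } else {
    w_norm <- pairs$w / m
  }
  tibble::tibble(a = pairs$a, b = pairs$b, category = "inparalog",
                 w = pairs$w, w_norm = w_norm)
}

#' Coortholog pairs between two genomes
#'
#' Duplication after speciation makes a set of inparalogs collectively
#' orthologous to genes of the other genome. A cross-genome pair (x in A,
#' z in B) is a coortholog candidate iff it is not itself an ortholog pair,
#' it is connected to an ortholog pair through inparalog links on either or
#' both sides (x inparalog of x' and/or z inparalog of z' with the primed
#' pair orthologous), and reciprocal hits x -> z and z -> x are present in
#' the two best-hit tables. Raw scores come from those hits; normalization
#' is per genome pair by the mean coortholog raw score.
#'
#' @param orthologs Ortholog pairs for the genome pair (columns `a`, `b`).
#' @param inparalogs_a,inparalogs_b Inparalog pairs of the two genomes
#'   (columns `a`, `b`).
#' @param best_ab,best_ba Best-hit tables of the two orderings.
#' @param config A [pipeline_config()]; returns an empty set when
#'   `include_coorthologs` is FALSE.
#' @return Tibble with columns `a`, `b`, `category` (`"coortholog"`), `w`,
#'   `w_norm`, sorted.
#' @export
find_coorthologs <- function(orthologs, inparalogs_a, inparalogs_b,
                             best_ab, best_ba,
                             config = pipeline_config()) {
  empty <- tibble::tibble(a = character(), b = character(),
                          category = character(), w = numeric(),
                          w_norm = numeric())
  if (!config$include_coorthologs || nrow(orthologs) == 0) return(empty)

  closure <- function(genes, inpar) {
    # gene -> itself plus its direct inparalog partners
    base <- tibble::tibble(from = genes, to = genes)
    if (nrow(inpar) == 0) return(base)
    links <- dplyr::bind_rows(
      tibble::tibble(from = inpar$a, to = inpar$b),
      tibble::tibble(from = inpar$b, to = inpar$a)
    )
    dplyr::distinct(dplyr::bind_rows(base,
                                     links[links$from %in% genes, ]))
  }
  side_a <- closure(unique(orthologs$a), inparalogs_a)
  side_b <- closure(unique(orthologs$b), inparalogs_b)

  cand <- orthologs[, c("a", "b")] |>
    dplyr::inner_join(side_a, by = c(a = "from"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(side_b, by = c(b = "from"),
                      relationship = "many-to-many") |>
    dplyr::transmute(a = .data$to.x, b = .data$to.y) |>
    dplyr::distinct() |>
    dplyr::anti_join(orthologs[, c("a", "b")], by = c("a", "b"))
  if (nrow(cand) == 0) return(empty)

  fwd <- tibble::tibble(a = best_ab$query, b = best_ab$subject,
                        nle_ab = best_ab$nle)
  bwd <- tibble::tibble(b = best_ba$query, a = best_ba$subject,
                        nle_ba = best_ba$nle)
  cand <- cand |>
    dplyr::inner_join(fwd, by = c("a", "b")) |>
    dplyr::inner_join(bwd, by = c("a", "b"))
  if (nrow(cand) == 0) return(empty)
  pairs <- tibble::tibble(a = cand$a, b = cand$b,
                          w = raw_score(cand$nle_ab, cand$nle_ba))
  pairs <- pairs[radix_order(pairs$a, pairs$b), , drop = FALSE]
  normalize_by_mean(pairs, "coortholog")
}

#' Read and write scored-pair tables
#'
#' Scored pairs are stored per genome (inparalogs) or per genome pair
#' (orthologs, coorthologs) as a 4-column TSV `a`, `b`, `w`, `w_norm` with a
#' header line, rows sorted, numbers serialized to round-trip exactly.
#'
#' @param pairs Tibble with columns `a`, `b`, `w`, `w_norm` (and optionally
#'   `category`, which is not serialized).
#' @param path File path.
#' @param category Category to stamp on the rows read back.
#' @return `write_scored_pairs()` returns `path` invisibly;
#'   `read_scored_pairs()` returns the tibble with a `category` column.
#' @export
write_scored_pairs <- function(pairs, path) {
  p <- pairs[radix_order(pairs$a, pairs$b), , drop = FALSE]
  lines <- c("a\tb\tw\tw_norm",
             sprintf("%s\t%s\t%s\t%s", p$a, p$b,
                     num_c17(p$w), num_c17(p$w_norm)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scored_pairs
#' @export
read_scored_pairs <- function(path, category) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  notify_file_open(path)
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "a\tb\tw\tw_norm") {
    stop("line 1 of ", path, ": missing scored-pair header", call. = FALSE)
  }
  body <- lines[-1][nzchar(lines[-1])]
  if (length(body) == 0) {
    return(tibble::tibble(a = character(), b = character(),
                          category = character(), w = numeric(),
                          w_norm = numeric()))
  }
  fields <- stringr::str_split(body, stringr::fixed("\t"))
  bad <- lengths(fields) != 4L
  if (any(bad)) {
    stop("line ", which(bad)[1] + 1L, " of ", path,
         ": expected 4 tab-separated fields", call. = FALSE)
  }
  m <- t(vapply(fields, identity, character(4)))
  w <- as.numeric(m[, 3]); w_norm <- as.numeric(m[, 4])
  if (anyNA(w) || anyNA(w_norm)) {
    stop("unparseable numeric field in ", path, call. = FALSE)
  }
  tibble::tibble(a = m[, 1], b = m[, 2], category = category,
                 w = w, w_norm = w_norm)
}
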