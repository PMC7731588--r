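#' Render and parse gene identifiers
#'
#' Genes are identified globally as `"taxon|local_id"`, where `taxon` is a
#' short alphanumeric genome code and `local_id` is unique within the genome.
#' This convention makes every downstream table self-describing about genome
#' membership: the genome of any gene can be recovered from its identifier
#' alone, without a lookup table.
#'
#' @param taxon Character vector of genome codes. Must be non-empty and must
#'   not contain `"|"` or whitespace.
#' @param local_id Character vector of within-genome gene identifiers. Must be
#'   non-empty and must not contain whitespace.
#' @return `render_gene_ref()` returns a character vector `"taxon|local_id"`.
#'   `parse_gene_ref()` returns a tibble with columns `taxon` and `local_id`,
#'   one row per input. `gene_taxon()` returns just the taxon codes.
#'   Rendering then parsing is the identity.
#' @examples
#' render_gene_ref("eco", "b0001")
#' parse_gene_ref("eco|b0001")
#' gene_taxon(c("eco|b0001", "stm|STM1"))
#' @export
render_gene_ref <- function(taxon, local_id) {
  taxon <- as.character(taxon)
  local_id <- as.character(local_id)
  bad_tax <- !nzchar(taxon) | grepl("[|[:space:]]", taxon)
  if (any(bad_tax)) {
    stop("invalid taxon code(s): ",
         paste(utils::head(taxon[bad_tax], 3), collapse = ", "),
         " (must be non-empty, no '|' or whitespace)", call. = FALSE)
  }
  bad_id <- !nzchar(local_id) | grepl("[[:space:]]", local_id)
  if (any(bad_id)) {
    stop("invalid local gene id(s): ",
         paste(utils::head(local_id[bad_id], 3), collapse = ", "),
         " (must be non-empty, no whitespace)", call. = FALSE)
  }
  paste0(taxon, "|", local_id)
}

#' @rdname render_gene_ref
#' @param x Character vector of rendered gene identifiers.
#' @export
parse_gene_ref <- function(x) {
  x <- as.character(x)
  n_sep <- lengths(regmatches(x, gregexpr("\\|", x)))
  bad <- n_sep != 1L
  if (any(bad)) {
    stop("malformed gene identifier(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "),
         " (expected exactly one '|' separator)", call. = FALSE)
  }
  parts <- stringr::str_split_fixed(x, stringr::fixed("|"), 2L)
  taxon <- parts[, 1L]
  local_id <- parts[, 2L]
  empty <- !nzchar(taxon) | !nzchar(local_id)
  if (any(empty)) {
    stop("malformed gene identifier(s): ",
         paste(utils::head(x[empty], 3), collapse = ", "),
         " (empty taxon or gene field)", call. = FALSE)
  }
  # re-validate through the renderer so parse(render(.)) == . is guaranteed
  render_gene_ref(taxon, local_id)
  tibble::tibble(taxon = taxon, local_id = local_id)
}

#' @rdname render_gene_ref
#' @export
gene_taxon <- function(x) {
  parse_gene_ref(x)$taxon
}

#' Pipeline configuration
#'
#' A single record housing every threshold of the pipeline. Defaults follow
#' the established conventions of reciprocal-best-hit orthology tools.
#'
#' @param evalue_exponent_cutoff Integer; a hit is kept when its E-value is
#'   at most `10^evalue_exponent_cutoff`. Default -5 (E-value <= 1e-5).
#' @param percent_match_cutoff Minimum percent match (alignment coverage of
#'   the shorter sequence, in percent). Default 50.
#' @param zero_evalue_cap Positive real; the -log10 value assigned to an
#'   E-value reported as exactly 0, and the upper bound on every -log10
#'   E-value. Default 181, near the smallest E-value exponent a search tool
#'   reports in double precision.
#' @param mcl_inflation Markov-clustering inflation exponent, > 1. Larger
#'   values give finer clusters. Default 1.5.
#' @param mcl_max_iterations Maximum expansion/inflation rounds. Default 200.
#' @param mcl_pruning_threshold Matrix entries below this are zeroed each
#'   round to keep the walk matrix sparse. Default 1e-8.
#' @param mcl_convergence_tol Iteration stops when the largest absolute
#'   entry change falls below this. Default 1e-8.
#' @param include_coorthologs Emit coortholog pairs? Default TRUE.
#' @param inparalog_norm_both If TRUE, the inparalog normalization constant
#'   averages only pairs where BOTH genes have an ortholog; default FALSE
#'   (at least one member suffices).
#' @param group_prefix,group_start_index Labeling of output groups, e.g.
#'   `"group1000"`. Defaults "group" and 1000.
#' @param rng_seed Seed for the synthetic-data module. Default 1.
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(mcl_inflation = 2)
#' cfg$evalue_exponent_cutoff
#' @export
pipeline_config <- function(evalue_exponent_cutoff = -5L,
                            percent_match_cutoff = 50,
                            zero_evalue_cap = 181,
                            mcl_inflation = 1.5,
                            mcl_max_iterations = 200L,
                            mcl_pruning_threshold = 1e-8,
                            mcl_convergence_tol = 1e-8,
                            include_coorthologs = TRUE,
                            inparalog_norm_both = FALSE,
                            group_prefix = "group",
                            group_start_index = 1000L,
                            rng_seed = 1L) {
  stopifnot(
    is.numeric(evalue_exponent_cutoff), length(evalue_exponent_cutoff) == 1,
    is.finite(evalue_exponent_cutoff),
    is.numeric(percent_match_cutoff), is.finite(percent_match_cutoff),
    is.numeric(zero_evalue_cap), zero_evalue_cap > 0,
    is.numeric(mcl_inflation), mcl_inflation > 1,
    mcl_max_iterations >= 1,
    mcl_pruning_threshold >= 0, mcl_convergence_tol > 0,
    is.logical(include_coorthologs), is.logical(inparalog_norm_both),
    is.character(group_prefix), length(group_prefix) == 1
  )
  structure(
    list(
      evalue_exponent_cutoff = as.integer(evalue_exponent_cutoff),
      percent_match_cutoff = as.numeric(percent_match_cutoff),
      zero_evalue_cap = as.numeric(zero_evalue_cap),
      mcl_inflation = as.numeric(mcl_inflation),
      mcl_max_iterations = as.integer(mcl_max_iterations),
      mcl_pruning_threshold = as.numeric(mcl_pruning_threshold),
      mcl_convergence_tol = as.numeric(mcl_convergence_tol),
      include_coorthologs = isTRUE(include_coorthologs),
      inparalog_norm_both = isTRUE(inparalog_norm_both),
      group_prefix = group_prefix,
      group_start_index = as.integer(group_start_index),
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

#' @exportS3Method base::print
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# byte-order (C locale) sort / order, used everywhere outputs must be
# reproducible across platforms and locales
radix_sort <- function(x) sort(x, method = "radix")
radix_order <- function(...) order(..., method = "radix")
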