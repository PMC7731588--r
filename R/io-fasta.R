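#' Read a proteome from an amino-acid FASTA file
#'
#' Each record's header must begin with a `"taxon|local_id"` gene identifier
#' (first whitespace-delimited token). Use [normalize_proteome_headers()] (or
#' the `taxon`/`id_field` arguments here) when headers follow some other
#' convention.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param taxon Optional genome code. When supplied, headers are normalized:
#'   the token selected by `id_field` becomes the local gene id and identities
#'   are rewritten as `"taxon|local_id"`.
#' @param id_field 1-based index of the header token (split on `"|"` and
#'   whitespace) used as the local id when `taxon` is given. Default 1.
#' @return A tibble with class `"proteome"` and columns `id` (gene
#'   identifier), `taxon`, `local_id`, `seq` (amino-acid string) and `length`
#'   (residues), in file order. The genome code is also stored in
#'   `attr(, "taxon")`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">eco|b1", "MKV", ">eco|b2", "MA"), fa)
#' read_proteome(fa)
#' @export
read_fasta <- function(path, taxon = NULL, id_field = 1L) {
  read_proteome(path, taxon = taxon, id_field = id_field)
}

#' @rdname read_fasta
#' @export
read_proteome <- function(path, taxon = NULL, id_field = 1L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # read without alphabet coercion so invalid residues are caught, not
  # silently dropped as readAAStringSet would do
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) {
    stop("empty FASTA file (no records): ", path, call. = FALSE)
  }
  headers <- names(aa)
  first_tok <- stringr::str_split_fixed(headers, "[[:space:]]+", 2L)[, 1L]
  if (is.null(taxon)) {
    parsed <- parse_gene_ref(first_tok)
    ids <- render_gene_ref(parsed$taxon, parsed$local_id)
    tax_col <- parsed$taxon
    if (length(unique(tax_col)) > 1) {
      stop("FASTA mixes taxa: ", paste(unique(tax_col), collapse = ", "),
           " — one proteome file per genome expected", call. = FALSE)
    }
    local <- parsed$local_id
    proteome_taxon <- tax_col[1L]
  } else {
    local <- select_header_field(headers, id_field)
    ids <- render_gene_ref(taxon, local)
    tax_col <- rep(taxon, length(ids))
    proteome_taxon <- taxon
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
         call. = FALSE)
  }
  seqs <- unname(as.character(aa))
  bad_alpha <- grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO*.\\-]",
                     toupper(seqs))
  if (any(bad_alpha)) {
    stop("non-amino-acid characters in sequence(s): ",
         paste(utils::head(ids[bad_alpha], 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seqs) < 1)) {
    stop("zero-length sequence(s): ",
         paste(utils::head(ids[nchar(seqs) < 1], 3), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    id = ids, taxon = tax_col, local_id = local,
    seq = unname(seqs), length = nchar(seqs)
  )
  attr(out, "taxon") <- proteome_taxon
  class(out) <- c("proteome", class(out))
  out
}

# split a FASTA header on "|" and whitespace, pick one token
select_header_field <- function(headers, id_field) {
  stopifnot(id_field >= 1)
  toks <- stringr::str_split(headers, "[|[:space:]]+")
  vapply(seq_along(toks), function(i) {
    tk <- toks[[i]][nzchar(toks[[i]])]
    if (id_field > length(tk)) {
      stop("header has no field ", id_field, ": \"", headers[i], "\"",
           call. = FALSE)
    }
    tk[id_field]
  }, character(1))
}

#' Rewrite proteome identities to the canonical taxon-prefixed form
#'
#' Mirrors the header-adjustment step users apply to raw database FASTA files
#' whose headers are `"|"`- or whitespace-delimited (e.g. `gi|123|ref|NP_1.1`):
#' one token is chosen as the local gene id and all identities become
#' `"taxon|local_id"`.
#'
#' @inheritParams read_fasta
#' @export
normalize_proteome_headers <- function(path, taxon, id_field = 1L) {
  read_proteome(path, taxon = taxon, id_field = id_field)
}

#' Write a proteome to FASTA
#'
#' @param proteome A proteome tibble from [read_proteome()] or
#'   [simulate_genomes()].
#' @param path Output file path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  aa <- Biostrings::AAStringSet(proteome$seq)
  names(aa) <- proteome$id
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Split a proteome into bounded query chunks
#'
#' All-against-all searches parallelize by splitting each genome's query
#' sequences into files of bounded size; each chunk is searched independently
#' against the full database. Concatenating the chunks reproduces the
#' proteome in order; every chunk has at most `chunk_size` records and all but
#' the last have exactly `chunk_size`.
#'
#' @param proteome A proteome tibble.
#' @param chunk_size Maximum records per chunk (>= 1).
#' @return A list of proteome tibbles (possibly empty).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">eco|b1", "MKV", ">eco|b2", "MA", ">eco|b3", "MW"), fa)
#' lengths(lapply(split_queries(read_proteome(fa), 2), nrow))
#' @export
split_queries <- function(proteome, chunk_size) {
  stopifnot(is.numeric(chunk_size), chunk_size >= 1)
  n <- nrow(proteome)
  if (n == 0) return(list())
  idx <- ceiling(seq_len(n) / chunk_size)
  unname(lapply(split(seq_len(n), idx), function(i) proteome[i, ]))
}

#' @rdname split_queries
#' @param out_dir Directory for the chunk FASTA files, created if needed.
#' @param prefix File-name prefix; chunks are named
#'   `"<prefix>.<k>.fasta"`.
#' @return `write_query_chunks()` returns the chunk file paths.
#' @export
write_query_chunks <- function(proteome, chunk_size, out_dir,
                               prefix = attr(proteome, "taxon")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chunks <- split_queries(proteome, chunk_size)
  paths <- character(length(chunks))
  for (k in seq_along(chunks)) {
    paths[k] <- file.path(out_dir, sprintf("%s.%d.fasta", prefix, k))
    write_proteome(chunks[[k]], paths[k])
  }
  paths
}

#' Gene lengths of one or more proteomes
#'
#' @param proteomes A proteome tibble or list of them.
#' @return A named numeric vector, gene identifier to length in residues.
#' @export
gene_lengths <- function(proteomes) {
  if (is.data.frame(proteomes)) proteomes <- list(proteomes)
  all <- dplyr::bind_rows(lapply(proteomes, function(p) p[c("id", "length")]))
  stats::setNames(as.numeric(all$length), all$id)
}
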