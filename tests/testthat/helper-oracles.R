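# Independent oracles and fixture builders. Each oracle re-derives its
# result by brute force (filter-then-group loops, dense matrices), sharing
# no code path with the implementation it checks.

# -- fixtures ---------------------------------------------------------------

# a minimal 12-column hit tibble from the essentials
make_hits <- function(query, subject, evalue, alignment_length,
                      pident = 90) {
  n <- length(query)
  tibble::tibble(
    query = query, subject = subject,
    pident = rep_len(pident, n),
    alignment_length = as.integer(rep_len(alignment_length, n)),
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = as.integer(rep_len(alignment_length, n)),
    sstart = 1L, send = as.integer(rep_len(alignment_length, n)),
    evalue = rep_len(evalue, n), bitscore = 50
  )
}

# randomized hit table for one query genome over >= 1 subject genomes, with
# engineered E-value ties and filter-straddling values
random_hit_table <- function(n_rows = 60, query_taxon = "aa",
                             subject_taxa = c("bb", "cc"),
                             genes_per_taxon = 8) {
  taxa <- c(query_taxon, subject_taxa)
  genes <- lapply(stats::setNames(taxa, taxa), function(tx)
    render_gene_ref(tx, sprintf("g%02d", seq_len(genes_per_taxon))))
  lengths <- stats::setNames(
    rep(100, genes_per_taxon * length(taxa)), unlist(genes))
  q <- sample(unname(genes[[query_taxon]]), n_rows, replace = TRUE)
  s <- sample(unname(unlist(genes)), n_rows, replace = TRUE)
  # discrete exponents make exact ties common; 1e-3/1e-4 straddle the filter
  ev <- 10^-sample(c(3, 4, 6, 10, 20, 30, 0), n_rows, replace = TRUE)
  ev[sample(n_rows, max(1, n_rows %/% 20))] <- 0  # some zero E-values
  alen <- sample(c(30, 49, 60, 90, 100), n_rows, replace = TRUE)
  list(hits = make_hits(q, s, ev, alen), lengths = lengths,
       genes = genes)
}

make_best_hit_table <- function(query, subject, nle,
                                query_taxon, subject_taxon, pm = 90) {
  out <- tibble::tibble(query = query, subject = subject,
                        nle = nle, pm = rep_len(pm, length(query)))
  attr(out, "query_taxon") <- query_taxon
  attr(out, "subject_taxon") <- subject_taxon
  out
}

make_pairs <- function(a, b, w_norm, category = "ortholog") {
  tibble::tibble(a = a, b = b, category = category, w_norm = w_norm)
}

# k disjoint uniform-weight cliques as a pair tibble
clique_pairs <- function(sizes, taxon = "xx", weight = 1) {
  out <- list()
  start <- 0L
  for (k in seq_along(sizes)) {
    genes <- render_gene_ref(taxon,
                             sprintf("n%03d", start + seq_len(sizes[k])))
    start <- start + sizes[k]
    cmb <- utils::combn(genes, 2)
    out[[k]] <- make_pairs(cmb[1, ], cmb[2, ], weight)
  }
  dplyr::bind_rows(out)
}

# -- oracle: best hits (filter all rows, group, argmin-with-ties) -----------

oracle_best_hits <- function(hits, lengths, config = pipeline_config(),
                             taxon) {
  rows <- list(between = list(), self = NULL)
  kept <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$query == h$subject) next
    pm <- min(100, 100 * h$alignment_length /
                min(lengths[[h$query]], lengths[[h$subject]]))
    if (!(h$evalue <= 10^config$evalue_exponent_cutoff &&
            pm >= config$percent_match_cutoff)) next
    nle <- if (h$evalue == 0) config$zero_evalue_cap else
      max(0, min(-log10(h$evalue), config$zero_evalue_cap))
    key <- paste(h$query, h$subject)
    rec <- list(query = h$query, subject = h$subject, nle = nle, pm = pm)
    if (is.null(kept[[key]]) || nle > kept[[key]]$nle ||
          (nle == kept[[key]]$nle && pm > kept[[key]]$pm)) {
      kept[[key]] <- rec
    }
  }
  df <- dplyr::bind_rows(lapply(kept, tibble::as_tibble))
  if (nrow(df) == 0) {
    empty <- tibble::tibble(query = character(), subject = character(),
                            nle = numeric(), pm = numeric())
    return(list(between = list(), self = empty))
  }
  stax <- sub("\\|.*$", "", df$subject)
  self <- df[stax == taxon, ]
  self <- self[order(self$query, self$subject, method = "radix"), ]
  between <- list()
  for (st in sort(unique(stax[stax != taxon]), method = "radix")) {
    b <- df[stax == st, ]
    keep <- logical(nrow(b))
    for (qg in unique(b$query)) {
      sel <- b$query == qg
      keep[sel] <- b$nle[sel] == max(b$nle[sel])
    }
    b <- b[keep, ]
    between[[st]] <- b[order(b$query, b$subject, method = "radix"), ]
  }
  list(between = between, self = self)
}

strip_bh <- function(tbl) {
  out <- tibble::as_tibble(tbl[, c("query", "subject", "nle", "pm")])
  attr(out, "query_taxon") <- NULL
  attr(out, "subject_taxon") <- NULL
  out[] <- lapply(out, unname)
  out
}

# -- oracle: reciprocal best pairs (double loop over cross pairs) -----------

oracle_rbp <- function(best_ab, best_ba) {
  out <- list()
  qs <- unique(best_ab$query)
  for (x in qs) {
    ys <- best_ab$subject[best_ab$query == x]
    for (y in ys) {
      xs_back <- best_ba$subject[best_ba$query == y]
      if (x %in% xs_back) {
        w <- (best_ab$nle[best_ab$query == x & best_ab$subject == y] +
                best_ba$nle[best_ba$query == y & best_ba$subject == x]) / 2
        out[[paste(x, y)]] <- tibble::tibble(a = x, b = y, w = w)
      }
    }
  }
  df <- dplyr::bind_rows(out)
  if (nrow(df) == 0) {
    return(tibble::tibble(a = character(), b = character(), w = numeric()))
  }
  df[order(df$a, df$b, method = "radix"), ]
}

# -- oracle: dense Markov clustering ----------------------------------------

dense_mcl <- function(edges, inflation = 1.5, max_iter = 200,
                      prune_thr = 1e-8, tol = 1e-8) {
  nodes <- sort(unique(c(edges$a, edges$b)), method = "radix")
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    M[edges$a[i], edges$b[i]] <- edges$weight[i]
    M[edges$b[i], edges$a[i]] <- edges$weight[i]
  }
  diag(M) <- pmax(1, apply(M, 1, max))
  norm <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.xmin), "/")
  M <- norm(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- norm(M2^inflation)
    M2[M2 < prune_thr] <- 0
    M2 <- norm(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  att <- which(diag(M) > 0)
  clusters <- lapply(att, function(i) nodes[M[i, ] > 0])
  # merge overlapping
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) length(intersect(m, cl)) > 0,
                        logical(1)))
    if (length(hit) == 0) {
      merged[[length(merged) + 1]] <- cl
    } else {
      merged[[hit[1]]] <- unique(c(unlist(merged[hit]), cl))
      merged <- merged[-hit[-1]]
    }
  }
  covered <- unlist(merged)
  for (x in setdiff(nodes, covered)) merged[[length(merged) + 1]] <- x
  lapply(merged, sort, method = "radix")
}

# canonical string form of a partition, for set comparison
partition_key <- function(clusters) {
  sort(unname(vapply(clusters, function(cl)
    paste(sort(cl, method = "radix"), collapse = " "), character(1))))
}

# checksum every file under a directory tree
tree_checksums <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  md5 <- tools::md5sum(file.path(dir, files))
  stats::setNames(unname(md5), files)
}

expect_same_pairs <- function(got, want) {
  g <- tibble::as_tibble(got[, c("a", "b", "w")])
  w <- tibble::as_tibble(want[, c("a", "b", "w")])
  g[] <- lapply(g, unname)
  w[] <- lapply(w, unname)
  expect_equal(g, w, ignore_attr = TRUE)
}
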