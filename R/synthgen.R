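#' Simulate proteomes with planted gene-family structure
#'
#' Generates a set of genomes sharing gene families with known ground truth,
#' for benchmarking every pipeline stage without external data. Each family
#' draws a random ancestral amino-acid sequence (length uniform on 80-400
#' residues) and a family-specific divergence level (uniform on 0.05-0.35
#' substitutions per site); each genome carries the family with probability
#' `1 - loss_prob` and, when present, gains an extra within-genome duplicate
#' with probability `duplication_prob`. Copies mutate independently from the
#' ancestor by point substitution at the family's divergence level
#' (duplicates slightly more). Deterministic given `seed`.
#'
#' @param n_genomes Number of genomes (>= 1). Default 5.
#' @param n_families Number of gene families (>= 1). Default 20.
#' @param duplication_prob Probability a present family carries a
#'   within-genome duplicate. Default 0.3.
#' @param loss_prob Probability a genome lacks a family. Default 0.1.
#' @param seed Integer RNG seed. Default 1.
#' @return A list with `proteomes` (named list of proteome tibbles, one per
#'   genome) and `truth`, a tibble of class `"planted_truth"` with columns
#'   `id`, `taxon`, `family`, `is_duplicate`, recording the planted family
#'   of every gene.
#' @examples
#' sim <- simulate_genomes(n_genomes = 2, n_families = 3, seed = 7)
#' sim$truth
#' @export
simulate_genomes <- function(n_genomes = 5, n_families = 20,
                             duplication_prob = 0.3, loss_prob = 0.1,
                             seed = 1L) {
  stopifnot(n_genomes >= 1, n_families >= 1,
            duplication_prob >= 0, duplication_prob < 1,
            loss_prob >= 0, loss_prob < 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(as.integer(seed), {
    taxa <- sprintf("tx%02d", seq_len(n_genomes))
    fam_len <- sample(80:400, n_families, replace = TRUE)
    fam_div <- stats::runif(n_families, 0.05, 0.35)
    fam_seq <- lapply(fam_len, function(L) sample(aa, L, replace = TRUE))
    mutate_seq <- function(anc, rate) {
      hit <- stats::runif(length(anc)) < rate
      if (any(hit)) anc[hit] <- sample(aa, sum(hit), replace = TRUE)
      paste(anc, collapse = "")
    }
    rows <- list()
    for (g in seq_len(n_genomes)) {
      for (f in seq_len(n_families)) {
        if (stats::runif(1) < loss_prob) next
        local <- sprintf("f%03da", f)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          taxon = taxa[g], local_id = local, family = f,
          is_duplicate = FALSE,
          seq = mutate_seq(fam_seq[[f]], fam_div[f])
        )
        if (stats::runif(1) < duplication_prob) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            taxon = taxa[g], local_id = sprintf("f%03db", f), family = f,
            is_duplicate = TRUE,
            seq = mutate_seq(fam_seq[[f]], fam_div[f] * 1.2)
          )
        }
      }
    }
    all <- dplyr::bind_rows(rows)
    all$id <- render_gene_ref(all$taxon, all$local_id)
    all$length <- nchar(all$seq)
    proteomes <- lapply(stats::setNames(taxa, taxa), function(tx) {
      p <- all[all$taxon == tx,
               c("id", "taxon", "local_id", "seq", "length")]
      attr(p, "taxon") <- tx
      class(p) <- c("proteome", class(p))
      p
    })
    truth <- all[, c("id", "taxon", "family", "is_duplicate")]
    attr(truth, "divergence") <- fam_div
    attr(truth, "seed") <- as.integer(seed)
    class(truth) <- c("planted_truth", class(truth))
    list(proteomes = proteomes, truth = truth)
  })
}

#' Emulate all-against-all similarity hit tables for simulated genomes
#'
#' Produces, for each genome, an individual-against-all hit table in the
#' 12-column tabular dialect, emulating what a protein similarity search
#' would report on the simulated proteomes — without running a search tool.
#' Every same-family ordered gene pair gets a hit whose -log10 E-value is a
#' monotone function of family divergence and the shorter sequence length,
#' plus Gaussian noise (`evalue_noise_sd`), floored at 10 so true homologs
#' always pass the default filter; the alignment covers 90% of the shorter
#' sequence. Within-genome duplicate pairs score systematically higher than
#' their cross-genome counterparts, so the inparalog rule has signal to
#' detect. Spurious cross-family hits appear at rate `background_hit_rate`
#' per ordered gene pair with -log10 E-values uniform on 1-9, deliberately
#' straddling the default E-value cutoff (5) so the acceptance filter has
#' discriminating work to do. Each gene also hits itself with E-value 0.
#' Deterministic given `seed`.
#'
#' @param proteomes Named list of proteome tibbles ([simulate_genomes()]).
#' @param truth The matching `"planted_truth"` tibble.
#' @param background_hit_rate Per ordered cross-family gene-pair probability
#'   of a spurious hit. Default 0.05.
#' @param evalue_noise_sd Standard deviation of the Gaussian noise on the
#'   -log10 E-value of true-homolog hits. Default 2.
#' @param seed Integer RNG seed; defaults to the truth's seed.
#' @return A named list of hit tibbles (12 columns, [read_hits()] shape),
#'   one per query genome.
#' @export
emulate_hit_tables <- function(proteomes, truth,
                               background_hit_rate = 0.05,
                               evalue_noise_sd = 2,
                               seed = attr(truth, "seed") %||% 1L) {
  stopifnot(background_hit_rate >= 0, background_hit_rate < 1,
            evalue_noise_sd >= 0)
  genes <- dplyr::bind_rows(lapply(proteomes, function(p)
    p[, c("id", "taxon", "length")]))
  info <- dplyr::left_join(genes, truth[, c("id", "family")], by = "id")
  if (anyNA(info$family)) stop("truth does not match proteomes",
                               call. = FALSE)
  div <- attr(truth, "divergence")
  withr::with_seed(as.integer(seed) + 7L, {
    # all ordered same-family pairs, distinct genes
    fam_pairs <- dplyr::inner_join(
      info, info, by = "family", suffix = c("_q", "_s"),
      relationship = "many-to-many"
    )
    fam_pairs <- fam_pairs[fam_pairs$id_q != fam_pairs$id_s, , drop = FALSE]
    minlen <- pmin(fam_pairs$length_q, fam_pairs$length_s)
    d <- div[fam_pairs$family]
    base <- pmin(160, 10 + (1 - d) * 0.45 * minlen)
    within <- fam_pairs$taxon_q == fam_pairs$taxon_s
    base[within] <- pmin(175, base[within] + 25)
    nle <- base + stats::rnorm(length(base), 0, evalue_noise_sd)
    nle <- pmin(pmax(nle, 10), 175)
    alen <- pmax(1L, as.integer(floor(0.9 * minlen)))
    pid <- round(pmin(100, pmax(15, 100 * (1 - d) +
                                  stats::rnorm(length(d), 0, 2))), 1)
    fam_hits <- tibble::tibble(
      query = fam_pairs$id_q, subject = fam_pairs$id_s, pident = pid,
      alignment_length = alen,
      mismatch = as.integer(round(alen * (1 - pid / 100))),
      gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L, send = alen,
      evalue = 10^(-nle), bitscore = round(2 * nle, 1)
    )
    # spurious cross-family hits
    bg_hits <- NULL
    if (background_hit_rate > 0) {
      n_genes <- nrow(info)
      idx <- expand.grid(q = seq_len(n_genes), s = seq_len(n_genes))
      idx <- idx[info$family[idx$q] != info$family[idx$s], , drop = FALSE]
      pick <- stats::runif(nrow(idx)) < background_hit_rate
      idx <- idx[pick, , drop = FALSE]
      if (nrow(idx) > 0) {
        minlen_b <- pmin(info$length[idx$q], info$length[idx$s])
        nle_b <- stats::runif(nrow(idx), 1, 9)
        alen_b <- pmax(1L, as.integer(floor(0.6 * minlen_b)))
        pid_b <- round(stats::runif(nrow(idx), 20, 35), 1)
        bg_hits <- tibble::tibble(
          query = info$id[idx$q], subject = info$id[idx$s], pident = pid_b,
          alignment_length = alen_b,
          mismatch = as.integer(round(alen_b * (1 - pid_b / 100))),
          gapopen = 0L, qstart = 1L, qend = alen_b, sstart = 1L,
          send = alen_b, evalue = 10^(-nle_b), bitscore = round(2 * nle_b, 1)
        )
      }
    }
    self_hits <- tibble::tibble(
      query = info$id, subject = info$id, pident = 100,
      alignment_length = as.integer(info$length), mismatch = 0L,
      gapopen = 0L, qstart = 1L, qend = as.integer(info$length),
      sstart = 1L, send = as.integer(info$length),
      evalue = 0, bitscore = round(2 * info$length, 1)
    )
    all_hits <- dplyr::bind_rows(fam_hits, bg_hits, self_hits)
    all_hits$query_taxon <- gene_taxon2(all_hits$query)
    all_hits <- all_hits[radix_order(all_hits$query, all_hits$subject), ,
                         drop = FALSE]
    out <- lapply(stats::setNames(names(proteomes), names(proteomes)),
                  function(tx) {
      h <- all_hits[all_hits$query_taxon == tx, , drop = FALSE]
      h$query_taxon <- NULL
      h
    })
    out
  })
}

#' Write a simulated benchmark to an input directory
#'
#' Convenience wrapper: simulates genomes, emulates hit tables, and writes
#' the `<taxon>.fasta` / `<taxon>.hits.tsv` files [run_pipeline()] expects,
#' plus a `truth.tsv` (gene, family, genome) for scoring.
#'
#' @inheritParams simulate_genomes
#' @inheritParams emulate_hit_tables
#' @param dir Output directory (created if needed).
#' @return The `"planted_truth"` tibble, invisibly.
#' @export
simulate_to_dir <- function(dir, n_genomes = 5, n_families = 20,
                            duplication_prob = 0.3, loss_prob = 0.1,
                            background_hit_rate = 0.05,
                            evalue_noise_sd = 2, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genomes(n_genomes, n_families, duplication_prob,
                          loss_prob, seed)
  hits <- emulate_hit_tables(sim$proteomes, sim$truth,
                             background_hit_rate, evalue_noise_sd, seed)
  for (tx in names(sim$proteomes)) {
    write_proteome(sim$proteomes[[tx]],
                   file.path(dir, paste0(tx, ".fasta")))
    write_hits(hits[[tx]], file.path(dir, paste0(tx, ".hits.tsv")))
  }
  tr <- sim$truth
  writeLines(c("gene\tfamily\tgenome",
               sprintf("%s\t%d\t%s", tr$id, tr$family, tr$taxon)),
             file.path(dir, "truth.tsv"))
  invisible(sim$truth)
}

#' Score recovery of planted families by predicted groups
#'
#' Compares a predicted clustering against the planted family assignment
#' with the adjusted Rand index and pairwise precision/recall of
#' co-clustering: precision is the fraction of co-clustered gene pairs that
#' are truly co-familial, recall the fraction of co-familial pairs that are
#' co-clustered. Truth genes missing from the prediction count as
#' singletons; predicted genes without truth are ignored.
#'
#' @param groups An `"ortho_groups"` tibble, an `"orthoflow_run"`, or a
#'   list of character vectors.
#' @param truth A `"planted_truth"` tibble.
#' @return A one-row tibble with columns `ari`, `precision`, `recall`,
#'   `n_genes`, `n_groups`.
#' @export
score_recovery <- function(groups, truth) {
  if (inherits(groups, "orthoflow_run")) groups <- groups$groups
  members <- if (is.data.frame(groups)) groups$members else groups
  pred <- rep(NA_integer_, nrow(truth))
  names(pred) <- truth$id
  for (k in seq_along(members)) {
    keep <- intersect(members[[k]], truth$id)
    pred[keep] <- k
  }
  # unassigned truth genes become singletons
  n_miss <- sum(is.na(pred))
  if (n_miss > 0) pred[is.na(pred)] <- length(members) + seq_len(n_miss)
  ct <- table(pred, truth$family)
  choose2 <- function(x) x * (x - 1) / 2
  both <- sum(choose2(ct))
  pred_pairs <- sum(choose2(rowSums(ct)))
  true_pairs <- sum(choose2(colSums(ct)))
  n <- sum(ct)
  expected <- pred_pairs * true_pairs / choose2(n)
  max_idx <- (pred_pairs + true_pairs) / 2
  ari <- if (max_idx == expected) 1 else (both - expected) / (max_idx - expected)
  tibble::tibble(
    ari = ari,
    precision = if (pred_pairs > 0) both / pred_pairs else 1,
    recall = if (true_pairs > 0) both / true_pairs else 1,
    n_genes = as.integer(n),
    n_groups = length(unique(pred))
  )
}
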