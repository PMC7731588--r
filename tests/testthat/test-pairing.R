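test_that("the raw pair score is the symmetric mean of the two directions", {
  expect_equal(raw_score(20, 30), 25)
  expect_equal(raw_score(0, 0), 0)
  expect_equal(raw_score(181, 181), 181)
  withr::with_seed(1, {
    a <- runif(1000, 0, 181); b <- runif(1000, 0, 181)
    expect_equal(raw_score(a, b), (a + b) / 2)
    expect_equal(raw_score(a, b), raw_score(b, a))
  })
  expect_error(raw_score(-1, 2))
})

test_that("reciprocal best pairs match the double-loop oracle, swap-invariant", {
  ab <- make_best_hit_table(c("aa|x"), c("bb|y"), 20, "aa", "bb")
  ba <- make_best_hit_table(c("bb|y"), c("aa|x"), 30, "bb", "aa")
  got <- reciprocal_best_pairs(ab, ba)
  expect_equal(got$w, 25)

  ba2 <- make_best_hit_table(c("bb|y"), c("aa|z"), 30, "bb", "aa")
  expect_equal(nrow(reciprocal_best_pairs(ab, ba2)), 0L)
  expect_error(reciprocal_best_pairs(ab, ab), "orderings")

  withr::with_seed(77, {
    for (rep in 1:40) {
      ga <- render_gene_ref("aa", sprintf("g%02d", 1:20))
      gb <- render_gene_ref("bb", sprintf("h%02d", 1:20))
      n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
      mk <- function(q, s, qt, st, n) {
        t <- tibble::tibble(query = sample(q, n, TRUE),
                            subject = sample(s, n, TRUE),
                            nle = sample(c(10, 20, 30), n, TRUE), pm = 90)
        t <- t[!duplicated(t[, c("query", "subject")]), ]
        # best-hit invariant: per query, keep ties at the max only
        t <- dplyr::group_by(t, query)
        t <- dplyr::ungroup(dplyr::filter(t, nle == max(nle)))
        attr(t, "query_taxon") <- qt; attr(t, "subject_taxon") <- st
        t
      }
      tab_ab <- mk(ga, gb, "aa", "bb", n1)
      tab_ba <- mk(gb, ga, "bb", "aa", n2)
      got <- reciprocal_best_pairs(tab_ab, tab_ba)
      expect_same_pairs(got, oracle_rbp(tab_ab, tab_ba))
      # swapping the argument order flips columns but not the pair set
      swapped <- reciprocal_best_pairs(tab_ba, tab_ab)
      expect_equal(partition_key(lapply(seq_len(nrow(got)), function(i)
                     c(got$a[i], got$b[i]))),
                   partition_key(lapply(seq_len(nrow(swapped)), function(i)
                     c(swapped$a[i], swapped$b[i]))))
      expect_equal(sort(swapped$w), sort(got$w))
    }
  })
})

test_that("ortholog normalization divides by the genome-pair mean", {
  pairs <- tibble::tibble(a = c("aa|x", "aa|y"), b = c("bb|p", "bb|q"),
                          w = c(10, 30))
  norm <- normalize_ortholog_scores(pairs)
  expect_equal(norm$w_norm, c(0.5, 1.5))
  expect_equal(norm$category, rep("ortholog", 2))

  single <- normalize_ortholog_scores(
    tibble::tibble(a = "aa|x", b = "bb|p", w = 7))
  expect_equal(single$w_norm, 1)

  withr::with_seed(9, {
    for (rep in 1:20) {
      p <- tibble::tibble(a = sprintf("aa|g%d", 1:30),
                          b = sprintf("bb|h%d", 1:30),
                          w = runif(30, 0, 181))
      expect_equal(mean(normalize_ortholog_scores(p)$w_norm), 1,
                   tolerance = 1e-12)
    }
  })

  expect_warning(
    z <- normalize_ortholog_scores(
      tibble::tibble(a = "aa|x", b = "bb|p", w = 0)),
    "zero")
  expect_equal(z$w_norm, 0)
})

test_that("between-genome cutoffs take the max over all best-hit tables", {
  t1 <- make_best_hit_table("aa|x", "bb|y", 20, "aa", "bb")
  t2 <- make_best_hit_table(c("aa|x", "aa|z"), c("cc|u", "cc|v"),
                            c(35, 12), "aa", "cc")
  cut <- inter_genome_cutoffs(list(t1, t2))
  expect_equal(cut[["aa|x"]], 35)
  expect_equal(cut[["aa|z"]], 12)
  expect_false("aa|w" %in% names(cut))
  expect_length(inter_genome_cutoffs(list()), 0L)

  withr::with_seed(31, {
    for (rep in 1:20) {
      tabs <- lapply(c("bb", "cc", "dd"), function(st) {
        n <- sample(5:20, 1)
        make_best_hit_table(render_gene_ref("aa", sample(letters, n, TRUE)),
                            render_gene_ref(st, as.character(1:n)),
                            runif(n, 5, 181), "aa", st)
      })
      got <- inter_genome_cutoffs(tabs)
      all <- dplyr::bind_rows(lapply(tabs, function(t)
        tibble::tibble(q = t$query, nle = t$nle)))
      want <- tapply(all$nle, all$q, max)
      expect_equal(got[sort(names(got), method = "radix")],
                   want[sort(names(want), method = "radix")],
                   ignore_attr = TRUE)
      expect_equal(sort(names(got)), sort(names(want)))
    }
  })
})

test_that("the inparalog rule requires reciprocity and the cutoff each way", {
  self <- make_best_hit_table(
    c("aa|x", "aa|y", "aa|p", "aa|u", "aa|v", "aa|m", "aa|n"),
    c("aa|y", "aa|x", "aa|q", "aa|v", "aa|u", "aa|n", "aa|m"),
    c(50, 48, 50, 30, 50, 44, 45), "aa", "aa")
  cutoffs <- c("aa|x" = 40, "aa|y" = 45, "aa|p" = 10, "aa|q" = 10,
               "aa|u" = 40, "aa|v" = 40, "aa|m" = 45, "aa|n" = 45)
  got <- find_inparalogs(self, cutoffs)
  # x-y: both directions above cutoffs -> kept with w = 49
  expect_true(any(got$a == "aa|x" & got$b == "aa|y"))
  expect_equal(got$w[got$a == "aa|x"], 49)
  # p-q: only one direction present -> rejected
  expect_false(any(got$a == "aa|p"))
  # u-v: u->v at 30 below u's cutoff 40 -> rejected
  expect_false(any(got$a == "aa|u"))
  # m-n: 44 < 45 one way -> rejected; ties at the cutoff WOULD qualify
  expect_false(any(got$a == "aa|m"))

  # ties qualify ("better" is >=)
  self_tie <- make_best_hit_table(c("aa|x", "aa|y"), c("aa|y", "aa|x"),
                                  c(40, 45), "aa", "aa")
  expect_equal(nrow(find_inparalogs(self_tie, cutoffs)), 1L)

  # genes with no between-genome hit get cutoff 0
  self_priv <- make_best_hit_table(c("aa|r", "aa|s"), c("aa|s", "aa|r"),
                                   c(8, 9), "aa", "aa")
  priv <- find_inparalogs(self_priv, c("aa|other" = 50))
  expect_equal(nrow(priv), 1L)
  expect_equal(priv$w, 8.5)

  # invariant to the row order of the self table
  withr::with_seed(4, {
    perm <- self[sample(nrow(self)), ]
    attr(perm, "query_taxon") <- "aa"; attr(perm, "subject_taxon") <- "aa"
    expect_equal(find_inparalogs(perm, cutoffs), got)
  })
})

test_that("inparalog normalization uses ortholog-linked pairs, with fallback", {
  pairs <- tibble::tibble(a = c("aa|p", "aa|r"), b = c("aa|q", "aa|s"),
                          w = c(10, 30))
  norm <- normalize_inparalog_scores(pairs, ortholog_genes = "aa|p")
  expect_equal(norm$w_norm, c(1, 3))
  expect_equal(norm$category, rep("inparalog", 2))

  fallback <- normalize_inparalog_scores(
    tibble::tibble(a = c("aa|p", "aa|r"), b = c("aa|q", "aa|s"),
                   w = c(8, 24)),
    ortholog_genes = character())
  expect_equal(fallback$w_norm, c(0.5, 1.5))

  single <- normalize_inparalog_scores(
    tibble::tibble(a = "aa|p", b = "aa|q", w = 12),
    ortholog_genes = "aa|p")
  expect_equal(single$w_norm, 1)

  # switch: require both members to have orthologs
  both_cfg <- pipeline_config(inparalog_norm_both = TRUE)
  norm_both <- normalize_inparalog_scores(pairs, c("aa|p", "aa|q"),
                                          both_cfg)
  expect_equal(norm_both$w_norm, c(1, 3))
  norm_both2 <- normalize_inparalog_scores(pairs, "aa|p", both_cfg)
  expect_equal(norm_both2$w_norm, c(0.5, 1.5))  # fallback: none qualify

  empty <- normalize_inparalog_scores(
    tibble::tibble(a = character(), b = character(), w = numeric()),
    character())
  expect_equal(nrow(empty), 0L)
})

test_that("coorthologs need an inparalog bridge and reciprocal hits", {
  ort <- tibble::tibble(a = "aa|x1", b = "bb|z")
  inpar_a <- tibble::tibble(a = "aa|x1", b = "aa|x2", w = 50)
  inpar_b <- tibble::tibble(a = character(), b = character(), w = numeric())
  ab <- make_best_hit_table(c("aa|x1", "aa|x2"), c("bb|z", "bb|z"),
                            c(40, 30), "aa", "bb")
  ba <- make_best_hit_table(c("bb|z", "bb|z"), c("aa|x1", "aa|x2"),
                            c(42, 28), "bb", "aa")
  co <- find_coorthologs(ort, inpar_a, inpar_b, ab, ba)
  expect_equal(co$a, "aa|x2")
  expect_equal(co$b, "bb|z")
  expect_equal(co$w, 29)          # (30 + 28) / 2
  expect_equal(co$w_norm, 1)      # self-normalized single pair
  expect_equal(co$category, "coortholog")

  # missing reverse hit blocks the pair
  ba_miss <- make_best_hit_table("bb|z", "aa|x1", 42, "bb", "aa")
  expect_equal(nrow(find_coorthologs(ort, inpar_a, inpar_b, ab, ba_miss)),
               0L)

  # the flag disables the category
  off <- pipeline_config(include_coorthologs = FALSE)
  expect_equal(nrow(find_coorthologs(ort, inpar_a, inpar_b, ab, ba, off)),
               0L)

  # ortholog pairs are never re-emitted as coorthologs
  co2 <- find_coorthologs(ort, inpar_a, inpar_b, ab, ba)
  expect_false(any(co2$a == "aa|x1" & co2$b == "bb|z"))
})

test_that("a relabeled genome copy pairs every gene with its twin only", {
  # genome bb is a copy of aa: symmetric scores, each gene's best hit in the
  # other genome is its own copy
  genes <- sprintf("g%02d", 1:8)
  withr::with_seed(12, nle <- runif(8, 20, 170))
  ab <- make_best_hit_table(render_gene_ref("aa", genes),
                            render_gene_ref("bb", genes), nle, "aa", "bb")
  ba <- make_best_hit_table(render_gene_ref("bb", genes),
                            render_gene_ref("aa", genes), nle, "bb", "aa")
  pairs <- reciprocal_best_pairs(ab, ba)
  expect_equal(nrow(pairs), 8L)
  expect_equal(parse_gene_ref(pairs$a)$local_id,
               parse_gene_ref(pairs$b)$local_id)
  expect_equal(pairs$w, nle)  # genes g01..g08 already in byte order
})
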