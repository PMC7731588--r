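test_that("graph assembly counts nodes/edges and applies precedence", {
  g <- build_graph(make_pairs(c("x|1", "x|1", "x|2"),
                              c("x|2", "y|1", "y|1"), 1))
  expect_equal(nrow(g), 3L)
  expect_length(attr(g, "nodes"), 3L)

  dup <- dplyr::bind_rows(
    make_pairs("x|1", "y|1", 2.0, "ortholog"),
    make_pairs("y|1", "x|1", 0.5, "coortholog"))
  g2 <- build_graph(dup)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$weight, 2.0)    # ortholog edge wins

  conflict <- dplyr::bind_rows(
    make_pairs("x|1", "y|1", 2.0, "ortholog"),
    make_pairs("x|1", "y|1", 1.0, "ortholog"))
  expect_error(build_graph(conflict), "conflicting")

  empty <- build_graph(make_pairs(character(), character(), numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("ABC graph files round-trip exactly and reject bad lines", {
  withr::with_seed(21, {
    n <- 100
    g <- build_graph(make_pairs(sprintf("x|a%03d", 1:n),
                                sprintf("y|b%03d", 1:n),
                                runif(n, 0, 3)))
    f <- withr::local_tempfile()
    write_abc(g, f)
    back <- read_abc(f)
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(g))
  })
  f <- withr::local_tempfile()
  writeLines("x|1\ty|1\t-0.5", f)
  expect_error(read_abc(f), "negative")
  writeLines("x|1\ty|1", f)
  expect_error(read_abc(f), "line 1")
})

test_that("disconnected cliques cluster exactly as themselves", {
  pairs <- clique_pairs(c(3, 3))
  res <- mcl_cluster(build_graph(pairs), inflation = 1.5)
  expect_true(res$converged)
  expect_equal(partition_key(res$clusters),
               partition_key(list(sprintf("xx|n%03d", 1:3),
                                  sprintf("xx|n%03d", 4:6))))

  single <- mcl_cluster(build_graph(make_pairs("x|a", "y|b", 1)))
  expect_equal(partition_key(single$clusters),
               partition_key(list(c("x|a", "y|b"))))
})

test_that("a weak bridge between cliques splits at the bridge", {
  pairs <- clique_pairs(c(4, 4))
  bridge <- make_pairs("xx|n001", "xx|n005", 0.01)
  g <- build_graph(dplyr::bind_rows(pairs, bridge))
  res <- mcl_cluster(g, inflation = 1.5)
  expect_equal(partition_key(res$clusters),
               partition_key(list(sprintf("xx|n%03d", 1:4),
                                  sprintf("xx|n%03d", 5:8))))
  # independent dense-matrix iteration agrees
  want <- dense_mcl(g, inflation = 1.5)
  expect_equal(partition_key(res$clusters), partition_key(want))
  # at much higher inflation the bridge still never merges the cliques
  res10 <- mcl_cluster(g, inflation = 10)
  expect_equal(partition_key(res10$clusters), partition_key(res$clusters))
})

test_that("clusterings agree with an independent dense iteration on random graphs", {
  withr::with_seed(88, {
    for (rep in 1:8) {
      n <- sample(8:16, 1)
      nodes <- render_gene_ref("zz", sprintf("m%02d", 1:n))
      cmb <- utils::combn(nodes, 2)
      keep <- runif(ncol(cmb)) < 0.35
      if (!any(keep)) keep[1] <- TRUE
      pairs <- make_pairs(cmb[1, keep], cmb[2, keep],
                          round(runif(sum(keep), 0.2, 2), 3))
      g <- build_graph(pairs)
      got <- mcl_cluster(g, inflation = 2)
      want <- dense_mcl(g, inflation = 2)
      expect_equal(partition_key(got$clusters), partition_key(want))
    }
  })
})

test_that("clusters partition the nodes and ignore insertion order", {
  withr::with_seed(55, {
    for (rep in 1:10) {
      pairs <- clique_pairs(sample(2:5, 3, replace = TRUE),
                            weight = round(runif(1, 0.5, 2), 2))
      g <- build_graph(pairs)
      res <- mcl_cluster(g)
      members <- unlist(res$clusters)
      expect_equal(sort(members), sort(attr(g, "nodes")))
      expect_false(anyDuplicated(members) > 0)

      perm <- pairs[sample(nrow(pairs)), ]
      res2 <- mcl_cluster(build_graph(perm))
      expect_equal(partition_key(res2$clusters),
                   partition_key(res$clusters))

      # uniform-weight cliques: clusters equal connected components
      ig <- igraph::graph_from_data_frame(g[, c("a", "b")],
                                          directed = FALSE)
      comp <- split(names(igraph::components(ig)$membership),
                    igraph::components(ig)$membership)
      expect_equal(partition_key(res$clusters), partition_key(comp))
    }
  })
})

test_that("column stochasticity is preserved through every iteration", {
  withr::with_seed(14, {
    pairs <- dplyr::bind_rows(
      clique_pairs(c(4, 3)),
      make_pairs("xx|n001", "xx|n005", 0.05))
    g <- build_graph(pairs)
    nodes <- attr(g, "nodes")
    n <- length(nodes)
    ia <- match(g$a, nodes); ib <- match(g$b, nodes)
    M <- Matrix::sparseMatrix(i = c(ia, ib, 1:n), j = c(ib, ia, 1:n),
                              x = c(g$weight, g$weight, rep(1, n)),
                              dims = c(n, n))
    M <- M %*% Matrix::Diagonal(x = 1 / Matrix::colSums(M))
    for (it in 1:30) {
      M <- M %*% M
      M <- methods::as(M, "CsparseMatrix"); M@x <- M@x^1.5
      M <- M %*% Matrix::Diagonal(x = 1 / Matrix::colSums(M))
      M <- methods::as(M, "CsparseMatrix"); M@x[M@x < 1e-8] <- 0
      M <- Matrix::drop0(M)
      M <- M %*% Matrix::Diagonal(x = 1 / Matrix::colSums(M))
      expect_true(all(abs(Matrix::colSums(M) - 1) < 1e-9))
      expect_true(all(M@x >= 0))
    }
  })
})

test_that("groups are numbered by size then smallest member and serialized", {
  groups <- to_groups(list(c("x|d", "x|e"), c("x|b", "x|a", "x|c")),
                      prefix = "group", start_index = 1000)
  expect_equal(groups$group_id, c("group1000", "group1001"))
  expect_equal(groups$members[[1]], c("x|a", "x|b", "x|c"))

  f <- withr::local_tempfile()
  write_groups(groups, f)
  expect_equal(readLines(f), c("group1000: x|a x|b x|c",
                               "group1001: x|d x|e"))
  expect_equal(read_groups(f), groups)

  # equal sizes: ordered by lexicographically smallest member
  tie <- to_groups(list(c("x|z", "x|y"), c("x|a", "x|b")))
  expect_equal(tie$members[[1]], c("x|a", "x|b"))

  write_groups(to_groups(list()), f)
  expect_equal(nrow(read_groups(f)), 0L)
})
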