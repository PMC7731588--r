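#' Assemble the similarity graph from scored pairs
#'
#' Collates ortholog, inparalog and coortholog pairs into one undirected
#' weighted graph: nodes are genes appearing in at least one pair, edge
#' weights are the normalized scores. When a pair was emitted both as an
#' ortholog and as a coortholog, the ortholog edge wins. Any other duplicate
#' with conflicting weights indicates an upstream bug and is an error.
#'
#' @param pairs Tibble of scored pairs (columns `a`, `b`, `category`,
#'   `w_norm`), e.g. the row-bound outputs of the pairing stage.
#' @return A tibble of class `"similarity_graph"` with columns `a`, `b`,
#'   `weight`, each unordered edge once (a < b), sorted; the node set is in
#'   `attr(, "nodes")`.
#' @export
build_graph <- function(pairs) {
  if (nrow(pairs) == 0) {
    g <- tibble::tibble(a = character(), b = character(), weight = numeric())
    attr(g, "nodes") <- character()
    class(g) <- c("similarity_graph", class(g))
    return(g)
  }
  stopifnot(all(c("a", "b", "category", "w_norm") %in% names(pairs)))
  if (any(pairs$w_norm < 0)) stop("negative edge weight", call. = FALSE)
  if (any(pairs$a == pairs$b)) stop("self-loop pair", call. = FALSE)
  e <- tibble::tibble(
    a = pmin(pairs$a, pairs$b),
    b = pmax(pairs$a, pairs$b),
    category = pairs$category,
    weight = pairs$w_norm
  )
  # ortholog beats coortholog on a shared pair
  rank <- c(ortholog = 1L, inparalog = 2L, coortholog = 3L)
  e$rank <- rank[e$category]
  e <- e[radix_order(e$a, e$b, e$rank), , drop = FALSE]
  first <- !duplicated(e[, c("a", "b")])
  dup <- e[!first, , drop = FALSE]
  kept <- e[first, , drop = FALSE]
  if (nrow(dup) > 0) {
    # precedence only resolves cross-category duplicates; a duplicate within
    # one category with a different weight is an upstream bug
    hit <- match(paste(dup$a, dup$b), paste(kept$a, kept$b))
    bad <- dup$category == kept$category[hit] & dup$weight != kept$weight[hit]
    if (any(bad)) {
      stop("conflicting duplicate edge(s), e.g. ", dup$a[bad][1], " -- ",
           dup$b[bad][1], call. = FALSE)
    }
  }
  g <- kept[, c("a", "b", "weight")]
  attr(g, "nodes") <- radix_sort(unique(c(g$a, g$b)))
  class(g) <- c("similarity_graph", class(g))
  g
}

#' Read and write graphs in ABC edge-list format
#'
#' The ABC format — one `node<tab>node<tab>weight` line per edge — is the
#' interchange format of the external `mcl` program. Edges are written
#' sorted, with weights serialized to round-trip exactly.
#'
#' @param graph A `"similarity_graph"` from [build_graph()].
#' @param path File path.
#' @return `write_abc()` returns `path` invisibly; `read_abc()` returns a
#'   `"similarity_graph"`.
#' @export
write_abc <- function(graph, path) {
  g <- graph[radix_order(graph$a, graph$b), , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s", g$a, g$b, num_c17(g$weight)), path)
  invisible(path)
}

#' @rdname write_abc
#' @export
read_abc <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path, call. = FALSE)
  notify_file_open(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(build_graph(tibble::tibble(a = character(), b = character(),
                                      category = character(),
                                      w_norm = numeric())))
  }
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  bad <- lengths(fields) != 3L
  if (any(bad)) {
    stop("line ", which(bad)[1], " of ", path,
         ": expected 3 tab-separated fields", call. = FALSE)
  }
  m <- t(vapply(fields, identity, character(3)))
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w)) {
    stop("line ", which(is.na(w))[1], " of ", path,
         ": unparseable weight", call. = FALSE)
  }
  if (any(w < 0)) {
    stop("line ", which(w < 0)[1], " of ", path, ": negative weight",
         call. = FALSE)
  }
  build_graph(tibble::tibble(a = m[, 1], b = m[, 2],
                             category = "ortholog", w_norm = w))
}

#' Markov clustering of a weighted similarity graph
#'
#' A deterministic sparse implementation of the Markov Cluster algorithm:
#' the graph becomes a column-stochastic flow matrix (after adding a
#' self-loop to each node weighted by its maximum incident edge weight, with
#' a minimum of 1 — the standard stabilization), and the iteration
#' alternates expansion (matrix squaring), inflation (entrywise power
#' `inflation` followed by column renormalization) and pruning (entries
#' below `pruning_threshold` zeroed, then renormalized) until the largest
#' absolute entry change drops below `convergence_tol` or `max_iterations`
#' is reached. Rows retaining positive diagonal mass are attractors; each
#' attractor's positive row support is a cluster, overlapping attractor
#' systems are merged, and any remaining node joins the attractor granting
#' it the largest flow (ties resolved by lexicographic node order), so the
#' clusters always partition the node set. Identical input always yields
#' identical output.
#'
#' @param graph A `"similarity_graph"` ([build_graph()] / [read_abc()]).
#' @param inflation Inflation exponent, > 1; larger is finer. Default 1.5.
#' @param max_iterations Iteration cap (default 200).
#' @param pruning_threshold Sparsity floor (default 1e-8).
#' @param convergence_tol Stop when the matrix stops changing by more than
#'   this (default 1e-8).
#' @return An object of class `"mcl_result"`: a list with `clusters` (list
#'   of character vectors, members sorted), `iterations`, `converged`,
#'   `inflation` and `n_nodes`.
#' @examples
#' g <- build_graph(tibble::tibble(
#'   a = c("x|1", "x|1", "x|2"), b = c("x|2", "y|1", "y|1"),
#'   category = "ortholog", w_norm = 1
#' ))
#' mcl_cluster(g)
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iterations = 200L,
                        pruning_threshold = 1e-8, convergence_tol = 1e-8) {
  stopifnot(inflation > 1)
  nodes <- attr(graph, "nodes")
  if (is.null(nodes)) nodes <- radix_sort(unique(c(graph$a, graph$b)))
  n <- length(nodes)
  if (n == 0) {
    return(new_mcl_result(list(), 0L, TRUE, inflation, 0L))
  }
  ia <- match(graph$a, nodes)
  ib <- match(graph$b, nodes)
  # symmetric adjacency with self-loops: loop weight = max incident, min 1
  loop <- rep(1, n)
  if (nrow(graph) > 0) {
    mx <- tapply(c(graph$weight, graph$weight), c(ia, ib), max)
    loop[as.integer(names(mx))] <- pmax(1, mx)
  }
  M <- Matrix::sparseMatrix(
    i = c(ia, ib, seq_len(n)),
    j = c(ib, ia, seq_len(n)),
    x = c(graph$weight, graph$weight, loop),
    dims = c(n, n)
  )
  M <- col_normalize(M)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iterations) {
    iterations <- iterations + 1L
    M_new <- M %*% M                        # expansion
    M_new <- inflate(M_new, inflation)      # inflation + renormalize
    M_new <- prune(M_new, pruning_threshold)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Markov clustering did not converge in ", max_iterations,
            " iterations; returning current clustering", call. = FALSE)
  }
  clusters <- interpret_attractors(M, nodes)
  new_mcl_result(clusters, iterations, converged, inflation, n)
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

inflate <- function(M, r) {
  M <- methods::as(M, "CsparseMatrix")
  M@x <- M@x^r
  col_normalize(M)
}

prune <- function(M, threshold) {
  M <- methods::as(M, "CsparseMatrix")
  M@x[M@x < threshold] <- 0
  col_normalize(Matrix::drop0(M))
}

# clusters from the converged flow matrix: attractor rows -> row supports,
# merged when overlapping; leftover nodes follow their largest inbound flow
interpret_attractors <- function(M, nodes) {
  n <- length(nodes)
  d <- Matrix::diag(M)
  attractors <- which(d > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  Ms <- methods::as(M, "TsparseMatrix")
  # union-find over attractor row supports
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  is_attr <- logical(n); is_attr[attractors] <- TRUE
  rows <- Ms@i + 1L; cols <- Ms@j + 1L; vals <- Ms@x
  keep <- is_attr[rows] & vals > 0
  rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
  # merge attractors sharing support (including attractor columns)
  for (k in seq_along(rows)) {
    if (is_attr[cols[k]]) union(rows[k], cols[k])
  }
  # assign each node to the attractor giving it the largest flow,
  # ties by lexicographically smallest attractor node
  assign_to <- integer(n)
  best_val <- rep(-Inf, n)
  ord <- radix_order(cols, nodes[rows])
  for (k in ord) {
    j <- cols[k]
    if (vals[k] > best_val[j]) {
      best_val[j] <- vals[k]
      assign_to[j] <- find(rows[k])
    }
  }
  for (a in attractors) assign_to[a] <- find(a)
  unassigned <- which(assign_to == 0L)
  assign_to[unassigned] <- unassigned   # singletons
  roots <- vapply(assign_to, find, integer(1))
  cl <- split(nodes, roots)
  unname(lapply(cl, radix_sort))
}

new_mcl_result <- function(clusters, iterations, converged, inflation, n) {
  structure(
    list(clusters = clusters, iterations = iterations,
         converged = converged, inflation = inflation, n_nodes = n),
    class = "mcl_result"
  )
}

#' @exportS3Method base::print
print.mcl_result <- function(x, ...) {
  cat(sprintf("<mcl_result> %d nodes in %d clusters (inflation %.3g, %d iterations%s)\n",
              x$n_nodes, length(x$clusters), x$inflation, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Cluster with an external mcl binary
#'
#' Escape hatch for users who prefer the reference `mcl` program: the graph
#' is written in ABC format, `mcl` is invoked with the given inflation, and
#' its native cluster output (one tab-separated cluster per line) is parsed.
#'
#' @inheritParams mcl_cluster
#' @param mcl_binary Path to the `mcl` executable.
#' @return An `"mcl_result"` (with `iterations = NA`).
#' @export
mcl_cluster_external <- function(graph, mcl_binary, inflation = 1.5) {
  if (Sys.which(mcl_binary) == "" && !file.exists(mcl_binary)) {
    stop("mcl binary not found: ", mcl_binary, call. = FALSE)
  }
  abc <- tempfile(fileext = ".abc")
  out <- tempfile(fileext = ".mcl")
  on.exit(unlink(c(abc, out)), add = TRUE)
  write_abc(graph, abc)
  status <- system2(mcl_binary,
                    c(abc, "--abc", "-I", format(inflation), "-o", out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("mcl exited with status ", status, call. = FALSE)
  lines <- readLines(out)
  clusters <- lapply(strsplit(lines, "\t", fixed = TRUE), radix_sort)
  new_mcl_result(clusters, NA_integer_, TRUE, inflation,
                 length(attr(graph, "nodes")))
}

#' Number clusters into ortholog groups
#'
#' Clusters are ordered by decreasing size (ties by lexicographically
#' smallest member), numbered from `start_index`, and labelled
#' `"<prefix><n>"`.
#'
#' @param clusters A list of character vectors, or an `"mcl_result"`.
#' @param prefix Group label prefix (default `"group"`).
#' @param start_index First group number (default 1000).
#' @return A tibble of class `"ortho_groups"` with columns `group_id`,
#'   `members` (list of sorted gene identifiers) and `size`.
#' @export
to_groups <- function(clusters, prefix = "group", start_index = 1000L) {
  if (inherits(clusters, "mcl_result")) clusters <- clusters$clusters
  clusters <- lapply(clusters, radix_sort)
  if (length(clusters) > 0) {
    smallest <- vapply(clusters, `[`, character(1), 1L)
    ord <- radix_order(-lengths(clusters), smallest)
    clusters <- clusters[ord]
  }
  out <- tibble::tibble(
    group_id = if (length(clusters)) {
      paste0(prefix, seq.int(start_index, length.out = length(clusters)))
    } else character(),
    members = clusters,
    size = lengths(clusters)
  )
  class(out) <- c("ortho_groups", class(out))
  out
}

#' Read and write ortholog-group files
#'
#' One group per line: `"<group_id>: member1 member2 ..."` with members
#' sorted.
#'
#' @param groups An `"ortho_groups"` tibble from [to_groups()].
#' @param path File path.
#' @return `write_groups()` returns `path` invisibly; `read_groups()`
#'   returns an `"ortho_groups"` tibble.
#' @export
write_groups <- function(groups, path) {
  lines <- sprintf("%s: %s", groups$group_id,
                   vapply(groups$members, paste, character(1),
                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path, call. = FALSE)
  notify_file_open(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(to_groups(list()))
  parts <- stringr::str_split_fixed(lines, stringr::fixed(": "), 2L)
  if (any(!nzchar(parts[, 1]) | !nzchar(parts[, 2]))) {
    stop("malformed group line in ", path, call. = FALSE)
  }
  members <- strsplit(parts[, 2], " ", fixed = TRUE)
  out <- tibble::tibble(group_id = parts[, 1],
                        members = lapply(members, radix_sort),
                        size = lengths(members))
  class(out) <- c("ortho_groups", class(out))
  out
}
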