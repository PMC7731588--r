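#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ortholog-group result into one row per gene
#'
#' @param x An `"ortho_groups"` tibble ([to_groups()], [read_groups()]).
#' @param ... Unused.
#' @return A tibble with columns `group_id`, `gene`, `taxon`.
#' @export
tidy.ortho_groups <- function(x, ...) {
  out <- tidyr::unnest(tibble::tibble(group_id = x$group_id,
                                      gene = x$members),
                       "gene")
  out$taxon <- gene_taxon2(out$gene)
  out
}

#' One-row summary of an ortholog-group result
#'
#' @param x An `"ortho_groups"` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_groups`, `n_genes`, `n_taxa`,
#'   `largest_group`, `median_size`, `n_singletons`.
#' @export
glance.ortho_groups <- function(x, ...) {
  genes <- unlist(x$members)
  tibble::tibble(
    n_groups = nrow(x),
    n_genes = length(genes),
    n_taxa = length(unique(gene_taxon2(genes))),
    largest_group = if (nrow(x)) max(x$size) else 0L,
    median_size = if (nrow(x)) stats::median(x$size) else NA_real_,
    n_singletons = sum(x$size == 1)
  )
}

#' @export
tidy.mcl_result <- function(x, ...) {
  to_groups(x) |> tidy()
}

#' @export
glance.mcl_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$clusters),
    n_nodes = x$n_nodes,
    iterations = x$iterations,
    converged = x$converged,
    inflation = x$inflation
  )
}

#' @export
tidy.orthoflow_run <- function(x, ...) {
  if (is.null(x$groups)) {
    stop("pipeline run has no groups (cluster stage not executed)",
         call. = FALSE)
  }
  tidy(x$groups)
}

#' @export
glance.orthoflow_run <- function(x, ...) {
  g <- if (is.null(x$groups)) glance(to_groups(list())) else glance(x$groups)
  dplyr::bind_cols(tibble::tibble(n_taxa_input = length(x$taxa)), g)
}

#' Plot the group-size distribution of an ortholog-group result
#'
#' @param object An `"ortho_groups"` tibble.
#' @param ... Unused.
#' @return A ggplot: counts of groups by member count.
#' @export
autoplot.ortho_groups <- function(object, ...) {
  df <- dplyr::count(tibble::tibble(size = object$size), .data$size)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "genes per group", y = "groups",
                  title = "Ortholog group sizes") +
    ggplot2::theme_minimal()
}

#' Plot the edge-weight distribution of a similarity graph
#'
#' @param object A `"similarity_graph"` ([build_graph()]).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot histogram of normalized edge weights.
#' @export
autoplot.similarity_graph <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tibble::tibble(weight = object$weight),
                  ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "normalized pair score", y = "edges",
                  title = "Similarity graph edge weights") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ortho_groups
#' @param groups An `"ortho_groups"` tibble.
#' @export
plot_group_sizes <- function(groups, ...) autoplot.ortho_groups(groups, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
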