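# Epistasis-network topology: graphs over genes with qualifying interactions
# and the summary statistics used to contrast stable and dynamic classes
# (average shortest path over connected pairs, average local clustering,
# average within-component closeness, degree distribution).

#' Build an epistasis graph
#'
#' Nodes are genes with at least one qualifying interaction; undirected,
#' unweighted edges are the qualifying gene pairs. Input is either a
#' records tibble (rows where `passes` is `TRUE` become edges; a tibble
#' without a `passes` column is taken as an explicit edge list) or an
#' [epistasis_stability()] table filtered to one class.
#'
#' @param records a tibble with `gene_a`, `gene_b` (optionally `passes`), or
#'   an `epistasis_stability` table (then `class_label` selects the class).
#' @param class_label optional stability class (`"stable"`, `"dynamic"`,
#'   `"intermediate"`) to filter an `epistasis_stability` input by; also
#'   stored on the graph.
#' @return An `igraph` undirected graph with a `class` attribute; edges are
#'   canonically sorted and deduplicated, self-loops dropped.
#' @export
build_epistasis_graph <- function(records, class_label = NULL) {
  df <- records
  if (inherits(records, "epistasis_stability") && !is.null(class_label)) {
    df <- records |> dplyr::filter(.data$class == class_label)
  } else if ("passes" %in% names(df)) {
    df <- df |> dplyr::filter(.data$passes)
  }
  edges <- df |>
    dplyr::transmute(a = pmin(.data$gene_a, .data$gene_b),
                     b = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::filter(.data$a != .data$b) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$a, .data$b)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "class", class_label %||% "all")
  g
}

#' Degree distribution table
#'
#' Degree histogram of an epistasis graph, with log10 columns for visual
#' comparison of exponential versus power-law decay (no formal model fit).
#'
#' @param graph an `igraph` graph.
#' @return A tibble: `degree`, `frequency`, `log10_degree`,
#'   `log10_frequency`.
#' @export
degree_distribution_table <- function(graph) {
  if (igraph::gorder(graph) == 0L) abort("empty graph has no degree distribution")
  deg <- igraph::degree(graph)
  tb <- table(deg)
  tibble(
    degree = as.integer(names(tb)),
    frequency = as.integer(tb)
  ) |>
    dplyr::mutate(
      log10_degree = ifelse(.data$degree > 0, log10(.data$degree), NA_real_),
      log10_frequency = log10(.data$frequency)
    )
}

#' Topology statistics of an epistasis graph
#'
#' Average shortest path length over connected ordered pairs only; average
#' local clustering coefficient (nodes of degree < 2 contribute 0); average
#' closeness, where each node's closeness is normalised within its connected
#' component (`(n_c - 1) / sum of distances`; the `"harmonic"` variant
#' averages reciprocal distances over all other nodes instead).
#'
#' @param graph an `igraph` graph with >= 2 nodes.
#' @param closeness `"component"` (default) or `"harmonic"`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `avg_path_length`,
#'   `avg_clustering`, `avg_closeness`.
#' @export
network_stats <- function(graph, closeness = c("component", "harmonic")) {
  closeness <- match.arg(closeness)
  n <- igraph::gorder(graph)
  if (n < 2L) abort("network_stats needs at least 2 nodes")
  D <- igraph::distances(graph)
  off <- D[upper.tri(D)]
  connected <- off[is.finite(off)]
  avg_path <- if (length(connected) > 0) mean(connected) else NA_real_

  cl <- igraph::transitivity(graph, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  avg_cl <- mean(cl)

  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- d[is.finite(d) & d > 0]
    if (closeness == "component") {
      if (length(reach) == 0L) 0 else length(reach) / sum(reach)
    } else {
      mean(c(1 / reach, rep(0, sum(is.infinite(d)))))
    }
  }, numeric(1))

  tibble(
    n_nodes = n,
    n_edges = igraph::gsize(graph),
    avg_path_length = avg_path,
    avg_clustering = avg_cl,
    avg_closeness = mean(clo)
  )
}
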