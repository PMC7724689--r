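# Scored undirected PPI graph: construction, topology metrics, summary
# statistics, hub ranking, Cytoscape-ready exports.
#
# The graph is undirected and unweighted for every metric; combined scores
# are used only for thresholding (a confidence cut, not an edge weight).

#' Build a scored protein-protein interaction graph
#'
#' Edge rows are filtered at `score_threshold` (kept when score >=
#' threshold), self-loops dropped, and duplicate pairs collapsed keeping the
#' maximum combined score (pairs are stored canonically, smaller label
#' first). Nodes of `node_universe` with no surviving edge are retained
#' unless `drop_isolated`; edge endpoints absent from the universe trigger a
#' warning but are retained.
#'
#' @param edge_table Data frame whose first two columns are node labels and
#'   which carries a `combined_score` column in \[0, 1\] (the STRING
#'   `string_interactions.tsv` dialect).
#' @param score_threshold Minimum combined score, default 0.4 ("medium
#'   confidence").
#' @param drop_isolated Drop nodes with no surviving edge.
#' @param node_universe Optional [gene_set()] or character vector of node
#'   labels to retain.
#' @return An object of class `ppi_graph`: list with `nodes` (character),
#'   `edges` (data frame `node1`, `node2`, `combined_score`) and
#'   `score_threshold`.
#' @export
build_graph <- function(edge_table, score_threshold = 0.4,
                        drop_isolated = FALSE, node_universe = NULL) {
  stopifnot(is.data.frame(edge_table))
  if (nrow(edge_table) > 0L) {
    sc <- edge_table$combined_score
    if (is.null(sc)) sc <- edge_table[[3L]]
    sc <- as.numeric(sc)
    if (anyNA(sc) || any(sc < 0 | sc > 1)) {
      stop("combined_score outside [0, 1]")
    }
    a <- as.character(edge_table[[1L]])
    b <- as.character(edge_table[[2L]])
  } else {
    a <- b <- character(0)
    sc <- numeric(0)
  }
  keep <- a != b                       # self-loops dropped
  a <- a[keep]; b <- b[keep]; sc <- sc[keep]
  n1 <- pmin(a, b); n2 <- pmax(a, b)   # canonical pair
  key <- paste(n1, n2, sep = "\r")
  if (anyDuplicated(key)) {
    sc <- stats::ave(sc, key, FUN = max)
    first <- !duplicated(key)
    n1 <- n1[first]; n2 <- n2[first]; sc <- sc[first]
  }
  keep <- sc >= score_threshold
  edges <- data.frame(node1 = n1[keep], node2 = n2[keep],
                      combined_score = sc[keep], stringsAsFactors = FALSE)
  universe <- if (inherits(node_universe, "gene_set")) node_universe$genes
              else as.character(node_universe)
  endpoints <- unique(c(edges$node1, edges$node2))
  if (length(universe) > 0L) {
    stray <- setdiff(unique(c(n1, n2)), universe)
    if (length(stray) > 0L) {
      warning(sprintf("%d edge node(s) absent from the universe, retained: %s",
                      length(stray),
                      paste(utils::head(stray, 5L), collapse = ", ")))
    }
    nodes <- unique(c(universe, endpoints))
  } else {
    nodes <- endpoints
  }
  if (drop_isolated) nodes <- nodes[nodes %in% endpoints]
  structure(list(nodes = nodes, edges = edges,
                 score_threshold = score_threshold),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph: %d nodes, %d edges (score >= %g)>\n",
              length(x$nodes), nrow(x$edges), x$score_threshold))
  invisible(x)
}

# igraph view of a ppi_graph (unweighted; score kept as edge attribute)
.as_igraph <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Topological-importance metrics per node
#'
#' For every node: `degree` (incident edge count), `betweenness`
#' (unnormalized shortest-path betweenness with equal splitting among
#' equal-length shortest paths; `betweenness_norm` divides by
#' `(n-1)(n-2)/2`), `closeness` (Wasserman-Faust component-scaled closeness
#' `(r/(n-1)) * (r/sum d)` where `r` is the number of other reachable nodes;
#' 0 for isolated nodes) and `coreness` (k-core index).
#'
#' @param g A [build_graph()] result.
#' @return Data frame `gene, degree, betweenness, betweenness_norm,
#'   closeness, coreness`, one row per node in graph node order.
#' @export
topology <- function(g) {
  ig <- .as_igraph(g)
  n <- length(g$nodes)
  deg <- igraph::degree(ig)
  btw <- igraph::betweenness(ig, directed = FALSE)
  btw_norm <- if (n > 2L) btw / (choose(n - 1L, 2L)) else rep(0, n)
  d <- igraph::distances(ig)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    fin <- is.finite(di)
    r <- sum(fin)
    if (r == 0L || n == 1L) return(0)
    (r / (n - 1L)) * (r / sum(di[fin]))
  }, numeric(1))
  data.frame(gene = g$nodes, degree = as.integer(deg),
             betweenness = as.numeric(btw),
             betweenness_norm = as.numeric(btw_norm),
             closeness = clo,
             coreness = as.integer(igraph::coreness(ig)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Network summary statistics
#'
#' `avg_degree = 2E/N` over retained nodes; `avg_shortest_path` is the mean
#' geodesic length over all unordered connected node pairs (disconnected
#' pairs are excluded and counted in `n_excluded_pairs`); `avg_clustering`
#' is the mean local clustering coefficient with 0 assigned to nodes of
#' degree < 2.
#'
#' @param g A [build_graph()] result with at least one node.
#' @return A list of class `network_summary`: `n_nodes`, `n_edges`,
#'   `avg_degree`, `avg_shortest_path` (NA when no pair is connected),
#'   `avg_clustering`, `n_excluded_pairs`.
#' @export
network_summary <- function(g) {
  stopifnot(inherits(g, "ppi_graph"))
  n <- length(g$nodes)
  if (n == 0L) stop("empty graph: no nodes")
  ig <- .as_igraph(g)
  m <- nrow(g$edges)
  d <- igraph::distances(ig)
  dv <- d[upper.tri(d)]
  connected <- is.finite(dv)
  asp <- if (any(connected)) mean(dv[connected]) else NA_real_
  cc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  structure(list(n_nodes = n, n_edges = m,
                 avg_degree = 2 * m / n,
                 avg_shortest_path = asp,
                 avg_clustering = if (n > 0L) mean(cc) else NA_real_,
                 n_excluded_pairs = sum(!connected)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "<network: %d nodes, %d edges | avg degree %.2f | avg path %.2f (%d pairs excluded) | avg clustering %.2f>\n",
    x$n_nodes, x$n_edges, x$avg_degree, x$avg_shortest_path,
    x$n_excluded_pairs, x$avg_clustering))
  invisible(x)
}

#' Rank hub nodes
#'
#' Deterministic ordering: degree descending, then betweenness descending,
#' then symbol ascending.
#'
#' @param topo A [topology()] table.
#' @return The same table, reordered.
#' @export
rank_hubs <- function(topo) {
  stopifnot(all(c("gene", "degree", "betweenness") %in% names(topo)))
  out <- topo[order(-topo$degree, -topo$betweenness, topo$gene,
                    method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a graph for Cytoscape
#'
#' `sif` writes `node1 pp node2` triples (isolated nodes as bare lines);
#' `tsv` mirrors the `string_interactions.tsv` dialect (`node1, node2,
#' combined_score`) with isolated nodes as rows whose `node2` and score are
#' `NA`, so `read_ppi_tsv(export_graph(g, "tsv"))` round-trips nodes, edges
#' and scores exactly; `graphml` delegates to [igraph::write_graph()].
#'
#' @param g A [build_graph()] result.
#' @param path Output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(g, "ppi_graph"))
  format <- match.arg(format)
  isolated <- setdiff(g$nodes, unique(c(g$edges$node1, g$edges$node2)))
  if (format == "sif") {
    lines <- c(sprintf("%s\tpp\t%s", g$edges$node1, g$edges$node2), isolated)
    writeLines(lines, path)
  } else if (format == "tsv") {
    df <- g$edges
    if (length(isolated) > 0L) {
      df <- rbind(df, data.frame(node1 = isolated, node2 = NA_character_,
                                 combined_score = NA_real_,
                                 stringsAsFactors = FALSE))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    igraph::write_graph(.as_igraph(g), path, format = "graphml")
  }
  invisible(path)
}

#' Read a graph exported as TSV
#'
#' Inverse of `export_graph(g, path, "tsv")`: rows with an empty second
#' column declare isolated nodes. No further thresholding is applied (the
#' stored edges already passed their construction cut).
#'
#' @param path File path.
#' @param score_threshold Threshold recorded on the returned graph.
#' @return A `ppi_graph`.
#' @export
read_ppi_tsv <- function(path, score_threshold = 0) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          na.strings = "")
  iso <- is.na(df$node2)
  build_graph(df[!iso, , drop = FALSE], score_threshold = score_threshold,
              node_universe = unique(c(df$node1, df$node2[!iso])))
}

#' Read a STRING-style interaction table
#'
#' Tolerates the `#node1` comment-style header STRING emits, and selects the
#' two node columns plus `combined_score`.
#'
#' @param path File path.
#' @return Data frame `node1, node2, combined_score` suitable for
#'   [build_graph()].
#' @export
read_string_edges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(df) <- sub("^X\\.", "", names(df))  # "#node1" -> "node1"
  if (!"combined_score" %in% names(df)) {
    stop(sprintf("'%s' has no combined_score column", path))
  }
  data.frame(node1 = as.character(df[[1L]]), node2 = as.character(df[[2L]]),
             combined_score = as.numeric(df$combined_score),
             stringsAsFactors = FALSE)
}
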