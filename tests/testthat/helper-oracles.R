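# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive every quantity from first principles (BFS,
# explicit path enumeration, iterative peeling, exhaustive hypergeometric
# sums) and never touch the package's implementation or igraph.

# adjacency list from an edge data frame over `nodes`
adj_list <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$node1[i]; b <- edges$node2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# single-source BFS distances (Inf when unreachable)
bf_bfs <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  queue <- src
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# enumerate every shortest s-t path as a vector of vertices
bf_shortest_paths <- function(adj, d_from_s, s, t) {
  if (is.infinite(d_from_s[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- names(adj)[vapply(names(adj), function(u)
      v %in% adj[[u]] && d_from_s[u] == d_from_s[v] - 1, logical(1))]
    out <- list()
    for (u in preds) {
      for (p in walk(u)) out[[length(out) + 1L]] <- c(p, v)
    }
    out
  }
  walk(t)
}

# unnormalized betweenness by explicit shortest-path enumeration
bf_betweenness <- function(nodes, edges) {
  adj <- adj_list(nodes, edges)
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  n <- length(nodes)
  for (i in seq_len(n - 1L)) {
    d <- bf_bfs(adj, nodes[i])
    for (j in seq.int(i + 1L, n)) {
      paths <- bf_shortest_paths(adj, d, nodes[i], nodes[j])
      if (length(paths) == 0L) next
      for (p in paths) {
        inner <- setdiff(p, c(nodes[i], nodes[j]))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

# Wasserman-Faust component-scaled closeness from BFS distances
bf_closeness <- function(nodes, edges) {
  adj <- adj_list(nodes, edges)
  n <- length(nodes)
  vapply(nodes, function(v) {
    d <- bf_bfs(adj, v)[setdiff(nodes, v)]
    r <- sum(is.finite(d))
    if (r == 0L || n == 1L) return(0)
    (r / (n - 1)) * (r / sum(d[is.finite(d)]))
  }, numeric(1))
}

# k-core index by iterative peeling
bf_coreness <- function(nodes, edges) {
  core <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (k in seq_len(length(nodes))) {
    alive <- nodes
    e <- edges
    repeat {
      deg <- stats::setNames(rep(0L, length(alive)), alive)
      if (nrow(e) > 0L) {
        tab <- table(c(e$node1, e$node2))
        deg[names(tab)] <- as.integer(tab)
      }
      drop <- alive[deg < k]
      if (length(drop) == 0L) break
      alive <- setdiff(alive, drop)
      e <- e[!(e$node1 %in% drop | e$node2 %in% drop), , drop = FALSE]
      if (length(alive) == 0L) break
    }
    core[alive] <- k
    if (length(alive) == 0L) break
  }
  core
}

# exact upper-tail hypergeometric by exhaustive binomial-coefficient sums
bf_hyper <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- seq.int(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# random simple graph fixture as an edge table over LETTERS-style labels
random_edges <- function(n, p = 0.35) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(node1 = pairs[keep, 1L], node2 = pairs[keep, 2L],
             combined_score = stats::runif(sum(keep), 0.4, 1),
             stringsAsFactors = FALSE)
}

path_graph <- function(labels) {
  data.frame(node1 = labels[-length(labels)], node2 = labels[-1L],
             combined_score = 1, stringsAsFactors = FALSE)
}

complete_graph <- function(labels) {
  pairs <- t(utils::combn(labels, 2L))
  data.frame(node1 = pairs[, 1L], node2 = pairs[, 2L], combined_score = 1,
             stringsAsFactors = FALSE)
}

star_graph <- function(center, leaves) {
  data.frame(node1 = center, node2 = leaves, combined_score = 1,
             stringsAsFactors = FALSE)
}

table2_path <- function() {
  system.file("extdata", "table2.tsv", package = "netpharm")
}

read_table2 <- function() {
  utils::read.delim(table2_path(), sep = "\t", quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
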