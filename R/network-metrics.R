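# Global attributes and centralities follow the conventions of Cytoscape's
# NetworkAnalyzer: unweighted topology by default (edge weights |r| are
# carried as attributes only), closeness = 1 / mean distance to reachable
# nodes, betweenness normalized by (n-1)(n-2)/2, local clustering of
# degree-<2 nodes counted as 0, centralization from the degree distribution.

.metric_weights <- function(g, weighted) {
  if (weighted) igraph::E(g)$weight else NA
}

#' Global attributes of a co-occurrence network
#'
#' Computes the standard whole-network summary used to compare turbidity
#' classes: mean clustering coefficient (local coefficient
#' `2 e_v / (k_v (k_v - 1))`, degree-<2 nodes contributing 0 by default),
#' degree-based network centralization
#' `(n / (n - 2)) * (k_max / (n - 1) - density)`, the number of ordered
#' node pairs connected by a finite path ("shortest paths"), the fraction
#' of such pairs, characteristic path length (mean finite pairwise
#' distance in hops), mean number of neighbors `2E / n`, network density
#' `2E / (n (n - 1))`, and network heterogeneity (coefficient of variation
#' of the degree distribution).
#'
#' @param net A [signed_network()] or igraph graph.
#' @param include_isolated Keep isolated nodes in the node set (default
#'   TRUE); with FALSE, attributes are computed on the degree-positive
#'   subgraph, the convention some NetworkAnalyzer runs use.
#' @param clustering_isolates `"zero"` (default: degree-<2 nodes enter the
#'   average as 0) or `"exclude"` (they are left out of the average).
#' @param weighted Use |r| edge weights as distances for the path-based
#'   attributes (default FALSE: pure topology, hops).
#' @return One-row data frame of class `global_network_attributes` with
#'   columns `n_nodes`, `n_edges`, `clustering_coefficient`,
#'   `network_centralization`, `shortest_paths_count`,
#'   `connected_pair_fraction`, `characteristic_path_length`,
#'   `mean_neighbors`, `density`, `heterogeneity`.
#' @examples
#' k4 <- signed_network(data.frame(source = c("a","a","a","b","b","c"),
#'                                 target = c("b","c","d","c","d","d")))
#' global_attributes(k4)
#' @export
global_attributes <- function(net, include_isolated = TRUE,
                              clustering_isolates = c("zero", "exclude"),
                              weighted = FALSE) {
  clustering_isolates <- match.arg(clustering_isolates)
  g <- as_igraph(net)
  if (!include_isolated) {
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes after the isolated-node policy")
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- 2 * m / (n * (n - 1))
  mean_neighbors <- mean(deg)
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  loc_zero <- ifelse(is.nan(loc), 0, loc)
  clustering <- if (clustering_isolates == "zero") {
    mean(loc_zero)
  } else if (all(is.nan(loc))) NA_real_ else mean(loc[!is.nan(loc)])
  centralization <- if (n < 3) NA_real_ else {
    (n / (n - 2)) * (max(deg) / (n - 1) - density)
  }
  D <- igraph::distances(g, weights = .metric_weights(g, weighted))
  off <- D[row(D) != col(D)]
  spc <- sum(is.finite(off))
  cpl <- if (spc > 0) mean(off[is.finite(off)]) else NA_real_
  md <- mean(deg)
  het <- if (md == 0) 0 else sqrt(max(mean(deg^2) - md^2, 0)) / md
  structure(data.frame(
    n_nodes = n, n_edges = m,
    clustering_coefficient = clustering,
    network_centralization = centralization,
    shortest_paths_count = spc,
    connected_pair_fraction = spc / (n * (n - 1)),
    characteristic_path_length = cpl,
    mean_neighbors = mean_neighbors,
    density = density,
    heterogeneity = het),
    class = c("global_network_attributes", "data.frame"))
}

#' Node centralities (degree, closeness, betweenness)
#'
#' Per-taxon centralities in the NetworkAnalyzer convention:
#' \describe{
#'   \item{ndc}{node degree centrality — the number of incident edges.}
#'   \item{ncc}{node closeness centrality — `1 / mean(distance to
#'     reachable nodes)`; 0 for isolated nodes. Equals 1 exactly when the
#'     node is adjacent to every node it can reach.}
#'   \item{nbc}{node betweenness centrality — shortest-path betweenness
#'     normalized to [0, 1] by `(n - 1)(n - 2) / 2`.}
#' }
#'
#' @param net A [signed_network()] or igraph graph.
#' @param weighted Use |r| weights as distances (default FALSE).
#' @return Data frame with columns `taxon`, `ndc`, `ncc`, `nbc`,
#'   `isolated`, one row per node.
#' @export
node_centralities <- function(net, weighted = FALSE) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  wts <- .metric_weights(g, weighted)
  D <- igraph::distances(g, weights = wts)
  ncc <- apply(D, 1L, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else 1 / mean(d)
  })
  nbc <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, weights = wts) /
      ((n - 1) * (n - 2) / 2)
  } else {
    rep(0, n)
  }
  data.frame(taxon = igraph::V(g)$name, ndc = as.integer(deg),
             ncc = as.numeric(ncc), nbc = as.numeric(nbc),
             isolated = deg == 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Edge betweenness centrality
#'
#' Unnormalized shortest-path edge betweenness: for each edge, the sum over
#' unordered connected node pairs (endpoint pairs included) of the fraction
#' of the pair's shortest paths that traverse the edge. High values mark
#' relationships critical to network integrity.
#'
#' @param net A [signed_network()] or igraph graph.
#' @param weighted Use |r| weights as distances (default FALSE).
#' @return Data frame with columns `source`, `target`, `r`, `sign`,
#'   `weight`, `ebc`.
#' @export
edge_betweenness_centrality <- function(net, weighted = FALSE) {
  g <- as_igraph(net)
  el <- network_edges(net)
  el$ebc <- if (nrow(el) > 0) {
    as.numeric(igraph::edge_betweenness(
      g, directed = FALSE, weights = .metric_weights(g, weighted)))
  } else {
    numeric(0)
  }
  el
}

# lexicographically smallest (min name, max name) key for each edge
.edge_keys <- function(g, eids) {
  ends <- igraph::ends(g, eids)
  paste(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]),
        sep = "\r")
}

#' Divisive edge-betweenness clustering (Girvan-Newman)
#'
#' Splits a network into sub-networks by repeatedly removing the edge of
#' maximum edge betweenness, recomputing after each removal. Stops when
#' the graph has `k` connected components, or, when `k` is `NULL`, returns
#' the partition of maximum modularity (computed on the original
#' topology) encountered along the full removal sequence. Ties in edge
#' betweenness are broken deterministically by lexicographic edge name.
#'
#' @param net A [signed_network()] or igraph graph with at least one edge.
#' @param k Target number of sub-networks, or `NULL` for the
#'   maximum-modularity partition.
#' @return Object of class `network_communities`: list with `membership`
#'   (named integer vector), `n_communities`, `modularity` (of the
#'   returned partition, on the original graph), and `removed_edges`
#'   (data frame of removals in order).
#' @export
network_communities <- function(net, k = NULL) {
  g0 <- as_igraph(net)
  if (igraph::ecount(g0) == 0) stop("network has no edges")
  n <- igraph::vcount(g0)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k > n) stop("k = ", k, " exceeds the number of nodes (", n, ")")
    if (k < 1) stop("k must be at least 1")
  }
  gw <- g0
  comp <- igraph::components(gw)
  if (!is.null(k) && comp$no > k) {
    stop("network already has ", comp$no, " components; cannot reach k = ", k)
  }
  part <- function(cw) {
    mem <- cw$membership
    list(membership = mem,
         modularity = igraph::modularity(
           g0, mem, weights = rep(1, igraph::ecount(g0))))
  }
  best <- part(comp)
  removed <- data.frame(source = character(0), target = character(0),
                        ebc = numeric(0), stringsAsFactors = FALSE)
  while (igraph::ecount(gw) > 0) {
    if (!is.null(k) && comp$no >= k) break
    eb <- igraph::edge_betweenness(gw, directed = FALSE, weights = NA)
    cand <- which(eb >= max(eb) - 1e-9)
    keys <- .edge_keys(gw, igraph::E(gw)[cand])
    pick <- cand[order(keys)[1L]]
    ends <- igraph::ends(gw, igraph::E(gw)[pick])
    removed <- rbind(removed, data.frame(source = ends[1L], target = ends[2L],
                                         ebc = eb[pick],
                                         stringsAsFactors = FALSE))
    gw <- igraph::delete_edges(gw, igraph::E(gw)[pick])
    comp <- igraph::components(gw)
    cur <- part(comp)
    if (is.null(k)) {
      if (cur$modularity > best$modularity + 1e-12) best <- cur
    } else {
      best <- cur
    }
  }
  if (!is.null(k) && comp$no != k) {
    stop("could not split into exactly k = ", k, " components")
  }
  structure(list(membership = best$membership,
                 n_communities = length(unique(best$membership)),
                 modularity = best$modularity,
                 removed_edges = removed),
            class = "network_communities")
}

#' @export
print.network_communities <- function(x, ...) {
  cat(sprintf("<network_communities> %d sub-network(s), modularity %.4f, %d edge(s) removed\n",
              x$n_communities, x$modularity, nrow(x$removed_edges)))
  invisible(x)
}
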