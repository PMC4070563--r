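## Topological characterisation battery: degree distribution and
## power-law fit, clustering coefficients, path metrics, betweenness,
## shared-neighbour statistics, components, density, hub and
## top-betweenness extraction, and list overlap.

#' Degree distribution
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return data.frame with columns \code{degree}, \code{frequency}
#'   (exact histogram of node degrees).
#' @export
degreeDistribution <- function(net) {
  d <- igraph::degree(asIgraph(net))
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)),
             frequency = as.integer(tab))
}

#' Log-log power-law fit of a degree distribution
#'
#' Ordinary least squares of log10(frequency) on log10(degree) over
#' degrees >= \code{min_degree} with non-zero frequency, the reading a
#' log-scale frequency plot implies.  The exponent is the negated
#' slope.
#'
#' @param dist data.frame with columns \code{degree}, \code{frequency}.
#' @param min_degree smallest degree entering the fit (default 1).
#' @return list with \code{exponent}, \code{intercept}, \code{r_squared}.
#' @export
powerlawFit <- function(dist, min_degree = 1) {
  d <- dist[dist$degree >= min_degree & dist$frequency > 0 &
              dist$degree > 0, , drop = FALSE]
  if (length(unique(d$degree)) < 3)
    stop("power-law fit needs at least 3 distinct degrees")
  fit <- lm(log10(frequency) ~ log10(degree), data = d)
  list(exponent = -unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Local clustering coefficients and the degree-grouped curve
#'
#' Node coefficient = 2 * triangles(node) / (deg * (deg - 1)), defined
#' as 0 for degree < 2.  The curve averages coefficients over nodes
#' grouped by their neighbour count.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return list with \code{per_node} (named numeric) and \code{curve}
#'   (data.frame: \code{degree}, \code{mean_clustering}, \code{n_nodes}).
#' @export
clusteringByDegree <- function(net) {
  g <- asIgraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  cc[deg < 2] <- 0
  names(cc) <- igraph::V(g)$name
  agg <- tapply(cc, deg, mean)
  curve <- data.frame(degree = as.integer(names(agg)),
                      mean_clustering = as.numeric(agg),
                      n_nodes = as.integer(table(deg)))
  list(per_node = cc, curve = curve)
}

#' Shortest-path distribution and closeness centrality
#'
#' Path lengths are BFS distances within components; the distribution
#' counts reachable ordered node pairs.  Closeness is
#' component-restricted: (number of reachable nodes) / (sum of
#' distances to them), 0 for isolated nodes.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return list with \code{distribution} (data.frame: \code{length},
#'   \code{frequency}) and \code{closeness} (named numeric in [0, 1]).
#' @export
pathMetrics <- function(net) {
  g <- asIgraph(net)
  d <- igraph::distances(g, weights = NA)   # hop counts, never edge weights
  finite <- is.finite(d) & d > 0
  lens <- d[finite]
  tab <- table(lens)
  cl <- vapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    ok <- is.finite(r) & r > 0
    if (!any(ok)) 0 else sum(ok) / sum(r[ok])
  }, numeric(1))
  names(cl) <- igraph::V(g)$name
  list(distribution = data.frame(length = as.integer(names(tab)),
                                 frequency = as.integer(tab)),
       closeness = cl)
}

#' Betweenness centrality (Brandes)
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param normalized divide by (n-1)(n-2)/2, the undirected pair count.
#' @return named numeric vector of betweenness values.
#' @export
betweennessAll <- function(net, normalized = FALSE) {
  g <- asIgraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (normalized) {
    n <- igraph::vcount(g)
    if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  }
  names(b) <- igraph::V(g)$name
  b
}

#' Shared-neighbour, neighbourhood-connectivity and topological
#' coefficient statistics
#'
#' Shared-neighbour distribution counts unordered node pairs by
#' |N(u) intersect N(v)|.  Neighbourhood connectivity of a node is the
#' mean degree of its neighbours (NA for isolated nodes).  The
#' topological coefficient of a node n with degree >= 2 is the mean of
#' J(n, m) / deg(n) over all partners m sharing at least one neighbour
#' with n, where J(n, m) = |shared neighbours| plus 1 if n and m are
#' adjacent; nodes of degree < 2 score 0.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return list with \code{shared_distribution} (data.frame:
#'   \code{shared}, \code{frequency}), \code{neighborhood_connectivity}
#'   and \code{topological_coefficient} (named numerics).
#' @export
neighborhoodStats <- function(net) {
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  storage.mode(A) <- "double"
  S <- A %*% A                      # S[u,v] = shared neighbour count
  deg <- rowSums(A)
  up <- upper.tri(S)
  tab <- table(S[up])
  nc <- as.numeric(A %*% deg) / deg
  nc[deg == 0] <- NA_real_
  J <- S + A
  tc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    partners <- which(S[i, ] > 0 & seq_len(n) != i)
    if (!length(partners)) return(0)
    mean(J[i, partners]) / deg[i]
  }, numeric(1))
  nm <- igraph::V(g)$name
  names(nc) <- names(tc) <- nm
  list(shared_distribution = data.frame(shared = as.integer(names(tab)),
                                        frequency = as.integer(tab)),
       neighborhood_connectivity = nc,
       topological_coefficient = tc)
}

#' Connected components
#'
#' @param net a non-empty \linkS4class{CoexpressionNetwork}.
#' @param member_threshold components with at least this many nodes are
#'   counted separately (default 6, matching the minimum module size).
#' @return list with \code{n_components}, \code{sizes} (descending),
#'   \code{n_at_threshold}, \code{main_nodes}, \code{main_edges},
#'   \code{main_edge_share} (fraction of all edges inside the main
#'   component).
#' @export
networkComponents <- function(net, member_threshold = 6) {
  g <- asIgraph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  main <- mainComponent(net)
  list(n_components = comp$no,
       sizes = sizes,
       n_at_threshold = sum(sizes >= member_threshold),
       main_nodes = nNodes(main),
       main_edges = nEdges(main),
       main_edge_share = if (nEdges(net) > 0)
         nEdges(main) / nEdges(net) else NA_real_)
}

#' Extract the main (largest) connected component
#'
#' Ties on component size are broken toward the component containing
#' the lexicographically smallest node id.
#'
#' @param net a non-empty \linkS4class{CoexpressionNetwork}.
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
mainComponent <- function(net) {
  g <- asIgraph(net)
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    firsts <- vapply(cand, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    cand <- cand[which.min(rank(firsts, ties.method = "first"))]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == cand[1]))
  asCoexpressionNetwork(sub)
}

#' Network density
#'
#' 2E / (n (n - 1)) for an undirected simple graph.  When interpreting
#' a printed edge count of unknown convention, use
#' \code{\link{densityFromCounts}} which exposes both the unordered and
#' the ordered-pair reading.
#'
#' @param net a \linkS4class{CoexpressionNetwork} with >= 2 nodes.
#' @return density in [0, 1].
#' @export
networkDensity <- function(net) {
  n <- nNodes(net)
  if (n < 2) stop("density needs at least 2 nodes")
  2 * nEdges(net) / (n * (n - 1))
}

#' Density from printed node/edge counts
#'
#' @param n_nodes node count.
#' @param edge_count printed edge count.
#' @param ordered is the printed count an ordered-pair count?  Reported
#'   module statistics whose density matches edge_count / (n (n - 1))
#'   are only consistent with the ordered reading.
#' @return density value.
#' @export
densityFromCounts <- function(n_nodes, edge_count, ordered = FALSE) {
  stopifnot(n_nodes >= 2)
  if (ordered) edge_count / (n_nodes * (n_nodes - 1))
  else 2 * edge_count / (n_nodes * (n_nodes - 1))
}

#' Hub extraction
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param min_degree inclusive degree cutoff (default 50, the Hub-50
#'   convention).
#' @return character vector of hub gene ids (lexicographic order).
#' @export
hubs <- function(net, min_degree = 50) {
  d <- igraph::degree(asIgraph(net))
  sort(names(d)[d >= min_degree])
}

#' Top-n nodes by betweenness centrality
#'
#' All nodes tied with the n-th value are included; ties are broken
#' lexicographically for ordering only.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param n nominal list length (default 90).
#' @return list with \code{genes} (ordered by decreasing betweenness,
#'   then id), \code{cutoff} (betweenness of the n-th node) and
#'   \code{n_returned}.
#' @export
topBetweenness <- function(net, n = 90) {
  b <- betweennessAll(net)
  if (length(b) == 0) return(list(genes = character(0), cutoff = NA, n_returned = 0L))
  n <- min(n, length(b))
  ord <- order(-b, names(b))
  cutoff <- b[ord][n]
  keep <- ord[b[ord] >= cutoff]
  list(genes = names(b)[keep], cutoff = unname(cutoff),
       n_returned = length(keep))
}

#' Overlap of a gene list with a reference list
#'
#' @param genes character vector.
#' @param reference character vector.
#' @return list with \code{intersection} (sorted), \code{n_overlap},
#'   \code{n_genes}, \code{n_reference}.
#' @export
overlapWithList <- function(genes, reference) {
  inter <- sort(intersect(genes, reference))
  list(intersection = inter, n_overlap = length(inter),
       n_genes = length(unique(genes)),
       n_reference = length(unique(reference)))
}

#' Full topology report
#'
#' Convenience wrapper bundling the whole battery for one network.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param hub_min_degree,top_n,member_threshold cutoffs passed through.
#' @return list of the individual metric results plus a \code{per_node}
#'   data.frame (degree, clustering, closeness, betweenness,
#'   topological coefficient, neighbourhood connectivity).
#' @export
topologyReport <- function(net, hub_min_degree = 50, top_n = 90,
                           member_threshold = 6) {
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  cbd <- clusteringByDegree(net)
  pm <- pathMetrics(net)
  bt <- betweennessAll(net)
  ns <- neighborhoodStats(net)
  per_node <- data.frame(gene_id = igraph::V(g)$name,
                         degree = as.integer(deg),
                         clustering = cbd$per_node,
                         closeness = pm$closeness,
                         betweenness = bt,
                         topological_coefficient = ns$topological_coefficient,
                         neighborhood_connectivity = ns$neighborhood_connectivity,
                         row.names = NULL)
  list(per_node = per_node,
       degree_distribution = degreeDistribution(net),
       clustering_curve = cbd$curve,
       path_distribution = pm$distribution,
       shared_neighbor_distribution = ns$shared_distribution,
       components = networkComponents(net, member_threshold),
       density = if (nNodes(net) >= 2) networkDensity(net) else NA_real_,
       hubs = hubs(net, hub_min_degree),
       top_betweenness = topBetweenness(net, top_n))
}
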