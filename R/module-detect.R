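## Module detection: FAG-EC agglomeration driven by edge clustering
## coefficients, Markov clustering (MCL), and module-size distribution
## analysis with a truncated power-law fit.

#' Edge clustering coefficients
#'
#' ECC(u, v) = (z + 1) / min(deg(u) - 1, deg(v) - 1), where z is the
#' number of triangles containing the edge (common neighbours of u and
#' v).  The "+1" keeps triangle-free regions rankable.  When either
#' endpoint has degree 1 the denominator vanishes and the ECC is
#' defined as 0.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return data.frame with columns \code{node1}, \code{node2},
#'   \code{ecc}; endpoints sorted within each edge.
#' @export
edgeClusteringCoefficient <- function(net) {
  g <- asIgraph(net)
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, as.integer)
  ecc <- numeric(nrow(el))
  z <- integer(nrow(el))
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    z[e] <- length(intersect(adj[[u]], adj[[v]]))
    denom <- min(deg[u], deg[v]) - 1
    ecc[e] <- if (denom <= 0) 0 else (z[e] + 1) / denom
  }
  a <- nm[el[, 1]]; b <- nm[el[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(node1 = a, node2 = b, ecc = ecc, triangles = z,
             stringsAsFactors = FALSE)
}

#' FAG-EC agglomerative module detection
#'
#' Fast agglomeration driven by edge clustering coefficients: starting
#' from singleton clusters, edges are processed in non-increasing ECC
#' order (ties broken lexicographically by sorted endpoint ids).  An
#' edge joining two distinct clusters merges them (the larger absorbs
#' the smaller) unless both clusters are already locked; a cluster
#' locks once its in-degree (2 x edges inside it, counted in the full
#' graph) exceeds lambda times its out-degree (edges leaving it).
#' Locked-locked merges are refused because each side already forms a
#' self-contained module.  Deterministic for a given network.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param lambda locking strictness, > 0 (default 1).
#' @param min_size smallest reported module (default 6).
#' @return a \linkS4class{ModuleSet}.
#' @export
fagecCluster <- function(net, lambda = 1, min_size = 6) {
  stopifnot(lambda > 0, min_size >= 1)
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (igraph::ecount(g) == 0 || n == 0)
    return(ModuleSet(list(), list(algorithm = "fagec", lambda = lambda,
                                  min_size = min_size)))
  ec <- edgeClusteringCoefficient(net)
  ord <- order(-ec$ecc, ec$node1, ec$node2)
  ec <- ec[ord, ]
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE)) > 0
  deg <- rowSums(A)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  members <- lapply(seq_len(n), identity)   # node indices per root
  int_edges <- numeric(n)                   # full-graph internal edges
  deg_sum <- deg                            # sum of member degrees
  locked <- rep(FALSE, n)
  is_locked <- function(r) {
    2 * int_edges[r] > lambda * (deg_sum[r] - 2 * int_edges[r])
  }
  idx <- match(ec$node1, nm)
  jdx <- match(ec$node2, nm)
  for (e in seq_len(nrow(ec))) {
    ru <- find(idx[e]); rv <- find(jdx[e])
    if (ru == rv) next
    # absorbing cluster = the larger; ties to the one holding the
    # lexicographically smallest node id
    su <- length(members[[ru]]); sv <- length(members[[rv]])
    if (su > sv) { big <- ru; small <- rv }
    else if (sv > su) { big <- rv; small <- ru }
    else {
      mu <- min(nm[members[[ru]]]); mv <- min(nm[members[[rv]]])
      if (mu <= mv) { big <- ru; small <- rv } else { big <- rv; small <- ru }
    }
    if (locked[big] && locked[small]) next
    cross <- sum(A[members[[big]], members[[small]], drop = FALSE])
    parent[small] <- big
    int_edges[big] <- int_edges[big] + int_edges[small] + cross
    deg_sum[big] <- deg_sum[big] + deg_sum[small]
    members[[big]] <- c(members[[big]], members[[small]])
    members[small] <- list(integer(0))
    locked[big] <- is_locked(big)
  }
  roots <- unique(vapply(seq_len(n), find, integer(1)))
  mods <- lapply(roots, function(r) sort(nm[members[[r]]]))
  mods <- mods[lengths(mods) >= min_size]
  ModuleSet(mods, list(algorithm = "fagec", lambda = lambda,
                       min_size = min_size))
}

#' Markov clustering (MCL)
#'
#' Column-stochastic random-walk matrix with unit self-loops, iterating
#' expansion (matrix squaring) and inflation (entrywise power then
#' column renormalisation) with pruning of entries below \code{tol}
#' until the matrix changes by less than \code{tol} or \code{max_iter}
#' is reached (warning on non-convergence).  Clusters are read from the
#' attractor structure; a node attracted by several attractor systems
#' is assigned to the larger cluster.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param inflation inflation exponent, > 1 (default 2).
#' @param max_iter iteration cap (default 100).
#' @param tol pruning and convergence threshold (default 1e-6).
#' @param min_size smallest reported module (default 1).
#' @return a \linkS4class{ModuleSet}.
#' @export
mclCluster <- function(net, inflation = 2, max_iter = 100, tol = 1e-6,
                       min_size = 1) {
  stopifnot(inflation > 1, min_size >= 1)
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n == 0)
    return(ModuleSet(list(), list(algorithm = "mcl", inflation = inflation,
                                  min_size = min_size)))
  M <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  storage.mode(M) <- "double"
  diag(M) <- 1
  normalize <- function(x) sweep(x, 2, pmax(colSums(x), .Machine$double.eps), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < tol] <- 0
    M2 <- normalize(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current partition")
  B <- M > tol
  attractors <- which(diag(M) > tol)
  if (!length(attractors)) attractors <- which(rowSums(B) > 0)
  # group attractors that feed one another into attractor systems
  sysid <- setNames(rep(NA_integer_, n), NULL)
  nextid <- 0L
  for (a in attractors) {
    linked <- attractors[B[a, attractors] | B[attractors, a]]
    ids <- unique(sysid[linked])
    ids <- ids[!is.na(ids)]
    if (!length(ids)) {
      nextid <- nextid + 1L
      sysid[a] <- nextid
    } else {
      keep <- min(ids)
      sysid[a] <- keep
      sysid[!is.na(sysid) & sysid %in% ids] <- keep
    }
    sysid[linked] <- sysid[a]
  }
  systems <- split(which(!is.na(sysid)), sysid[!is.na(sysid)])
  clusters <- lapply(systems, function(as)
    sort(unique(c(as, which(colSums(B[as, , drop = FALSE]) > 0)))))
  # resolve overlapping assignments toward the larger cluster
  ord <- order(-lengths(clusters))
  assigned <- rep(FALSE, n)
  final <- list()
  for (ci in ord) {
    mem <- setdiff(clusters[[ci]], which(assigned))
    if (length(mem)) {
      final[[length(final) + 1L]] <- sort(nm[mem])
      assigned[mem] <- TRUE
    }
  }
  un <- which(!assigned)
  for (u in un) final[[length(final) + 1L]] <- nm[u]
  final <- final[lengths(final) >= min_size]
  ModuleSet(final, list(algorithm = "mcl", inflation = inflation,
                        tol = tol, min_size = min_size))
}

#' Module-size distribution and truncated power-law fit
#'
#' Histogram of module sizes plus, when at least three distinct sizes
#' are present, a least-squares fit of
#' log f(s) = log c - alpha log s - s / beta
#' (power law with exponential truncation).
#'
#' @param ms a \linkS4class{ModuleSet}.
#' @return list with \code{distribution} (data.frame: \code{size},
#'   \code{frequency}), \code{fit} (list alpha, beta, r_squared) or
#'   \code{NULL}, and \code{fit_available} flag.
#' @export
moduleSizeDistribution <- function(ms) {
  sz <- moduleSizes(ms)
  tab <- table(sz)
  dist <- data.frame(size = as.integer(names(tab)),
                     frequency = as.integer(tab))
  if (nrow(dist) < 3)
    return(list(distribution = dist, fit = NULL, fit_available = FALSE))
  d <- dist
  fit <- lm(log(frequency) ~ log(size) + size, data = d)
  co <- coef(fit)
  list(distribution = dist,
       fit = list(alpha = -unname(co["log(size)"]),
                  beta = -1 / unname(co["size"]),
                  r_squared = summary(fit)$r.squared),
       fit_available = TRUE)
}

#' Rand index between two partitions
#'
#' Agreement of pair co-membership between a detected
#' \linkS4class{ModuleSet} (or membership vector) and a reference
#' partition, over the genes present in both.
#'
#' @param a,b \linkS4class{ModuleSet}s or named membership vectors.
#' @return Rand index in [0, 1].
#' @export
randIndex <- function(a, b) {
  toMembership <- function(x) {
    if (is(x, "ModuleSet")) {
      mods <- moduleList(x)
      setNames(rep(seq_along(mods), lengths(mods)),
               unlist(mods, use.names = FALSE))
    } else x
  }
  ma <- toMembership(a); mb <- toMembership(b)
  common <- intersect(names(ma), names(mb))
  if (length(common) < 2) stop("fewer than 2 genes in common")
  ma <- ma[common]; mb <- mb[common]
  n <- length(common)
  pairs <- combn(n, 2)
  same_a <- ma[pairs[1, ]] == ma[pairs[2, ]]
  same_b <- mb[pairs[1, ]] == mb[pairs[2, ]]
  mean(same_a == same_b)
}
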