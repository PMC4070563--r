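## Independent brute-force oracles used by the property tests.  These
## follow the metric definitions directly (Floyd-Warshall distances,
## sigma-counting betweenness, definitional loops) and deliberately
## share no code with the package implementations.

# Adjacency matrix -> named node ids.
oracleNodeIds <- function(n) sprintf("n%02d", seq_len(n))

# Build a CoexpressionNetwork from a 0/1 adjacency matrix.
netFromAdjacency <- function(A) {
  n <- nrow(A)
  ids <- oracleNodeIds(n)
  sel <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- if (nrow(sel)) cbind(ids[sel[, 1]], ids[sel[, 2]]) else NULL
  CoexpressionNetwork(ids, edges)
}

# Every labelled graph on n <= 4 nodes, plus seeded random graphs on
# n = 5..8 across densities.
oracleGraphSuite <- function() {
  gs <- list()
  for (n in 1:4) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (mask in 0:(2^nrow(pairs) - 1)) {
      A <- matrix(0L, n, n)
      if (nrow(pairs)) {
        on <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
        for (e in on) {
          A[pairs[e, 1], pairs[e, 2]] <- 1L
          A[pairs[e, 2], pairs[e, 1]] <- 1L
        }
      }
      gs[[length(gs) + 1L]] <- A
    }
  }
  set.seed(20240915)
  for (n in 5:8) {
    for (p in c(0.15, 0.3, 0.5, 0.7, 0.85, 0.95)) {
      for (rep in 1:2) {
        A <- matrix(0L, n, n)
        up <- which(upper.tri(A))
        A[up] <- as.integer(runif(length(up)) < p)
        A <- A + t(A)
        gs[[length(gs) + 1L]] <- A
      }
    }
  }
  gs
}

# All-pairs hop distances by Floyd-Warshall.
bruteDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Betweenness from the definition: sum over pairs (s, t) of the
# fraction of shortest s-t paths through v, with path counts sigma
# built level by level from the distance matrix.
bruteBetweenness <- function(A, D = bruteDistances(A)) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ds <- D[s, ]
    levels <- sort(unique(ds[is.finite(ds) & ds > 0]))
    for (lev in levels) {
      for (v in which(ds == lev)) {
        preds <- which(A[, v] == 1 & ds == lev - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  b
}

# Local clustering, closeness, neighbourhood connectivity, topological
# coefficient, shared-neighbour pair counts -- all from the definitions.
bruteNodeMetrics <- function(A) {
  n <- nrow(A)
  D <- bruteDistances(A)
  deg <- rowSums(A)
  clus <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  close <- vapply(seq_len(n), function(i) {
    r <- D[i, -i]
    ok <- is.finite(r) & r > 0
    if (!any(ok)) 0 else sum(ok) / sum(r[ok])
  }, numeric(1))
  nc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (!length(nb)) NA_real_ else mean(deg[nb])
  }, numeric(1))
  shared <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    shared[i, j] <- length(intersect(which(A[i, ] == 1), which(A[j, ] == 1)))
  tc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    partners <- which(shared[i, ] > 0 & seq_len(n) != i)
    if (!length(partners)) return(0)
    mean(shared[i, partners] + A[i, partners]) / deg[i]
  }, numeric(1))
  shared_pairs <- shared[upper.tri(shared)]
  comp_of <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp_of[i] == 0L) {
      cid <- cid + 1L
      comp_of[is.finite(D[i, ])] <- cid
    }
  }
  list(degree = deg, clustering = clus, closeness = close,
       betweenness = bruteBetweenness(A, D),
       neighborhood_connectivity = nc, topological_coefficient = tc,
       shared_pairs = shared_pairs,
       path_lengths = D[is.finite(D) & D > 0],
       components = comp_of,
       density = if (n >= 2) sum(A) / (n * (n - 1)) else NA_real_)
}

# Mutual-kNN edge oracle via an independent formulation of the tied
# k-list: j is in i's list iff fewer than k partners beat w[i, j].
bruteMknnEdges <- function(w, k, tol = 1e-12) {
  n <- nrow(w)
  diag(w) <- NA_real_
  inList <- function(i, j) {
    !is.na(w[i, j]) && sum(w[i, ] > w[i, j] + tol, na.rm = TRUE) < k
  }
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (inList(i, j) && inList(j, i)) out[[length(out) + 1L]] <- c(i, j)
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

# ARACNE DPI oracle: explicit unordered-triple scan.
bruteDpi <- function(w, mode, tolr) {
  n <- nrow(w)
  rem <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (k in setdiff(seq_len(n), c(i, j))) {
      mn <- min(w[i, k], w[j, k])
      drop <- if (mode == "additive") w[i, j] < mn - tolr
              else w[i, j] < tolr * mn
      if (drop) { rem[i, j] <- rem[j, i] <- TRUE; break }
    }
  }
  out <- w
  out[rem] <- 0
  diag(out) <- 0
  out
}

# CLR oracle from the definition.
bruteClr <- function(w) {
  n <- nrow(w)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- w[i, -i]
    mu <- mean(row); sg <- sd(row)
    for (j in seq_len(n)) if (j != i && sg > 0)
      z[i, j] <- max(0, (w[i, j] - mu) / sg)
  }
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  dimnames(out) <- dimnames(w)
  out
}

# MRNET oracle: per-target forward MRMR selection written longhand.
bruteMrnet <- function(w) {
  n <- nrow(w)
  out <- matrix(0, n, n, dimnames = dimnames(w))
  for (y in seq_len(n)) {
    selected <- integer(0)
    remaining <- setdiff(seq_len(n), y)
    repeat {
      scores <- vapply(remaining, function(x) {
        red <- if (length(selected)) mean(w[x, selected]) else 0
        w[x, y] - red
      }, numeric(1))
      if (!length(scores) || max(scores) <= 0) break
      b <- remaining[which.max(scores)]
      out[b, y] <- max(out[b, y], max(scores))
      selected <- c(selected, b)
      remaining <- setdiff(remaining, b)
    }
  }
  out <- pmax(out, t(out))
  diag(out) <- 0
  out
}

# Kraskov estimator written longhand (full sort per point).
bruteKraskov <- function(x, y, k) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    dmax <- pmax(abs(x - x[i]), abs(y - y[i]))[-i]
    eps <- sort(dmax)[k]
    nx <- sum(abs(x - x[i]) < eps) - 1
    ny <- sum(abs(y - y[i]) < eps) - 1
    s <- s + digamma(nx + 1) + digamma(ny + 1)
  }
  digamma(k) + digamma(n) - s / n
}

# Random symmetric positive similarity matrix (MI-like).
randomMiMatrix <- function(n, seed) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- list(oracleNodeIds(n), oracleNodeIds(n))
  w
}

# Planted-partition graph: k blocks, within-block edge prob p_in,
# between-block p_out; returns list(net, membership).
plantedPartitionGraph <- function(block_sizes, p_in, p_out, seed) {
  set.seed(seed)
  n <- sum(block_sizes)
  member <- rep(seq_along(block_sizes), block_sizes)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (member[i] == member[j]) p_in else p_out
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1L
  }
  ids <- sprintf("g%03d", seq_len(n))
  sel <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  net <- CoexpressionNetwork(ids, cbind(ids[sel[, 1]], ids[sel[, 2]]))
  list(net = net, membership = setNames(member, ids))
}
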