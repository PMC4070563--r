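## Linear co-expression inference: all-pairs Pearson correlation with
## either a fixed signed threshold or the modified mutual k-nearest
## neighbour (mKNN) edge rule in which the k-list keeps the k-1 best
## partners plus every gene tied at the k-th correlation value.

#' All-pairs Pearson correlation
#'
#' Standard sample correlation between every pair of gene profiles.
#' Genes whose profile has zero variance get \code{NA} against every
#' partner; \code{NA} similarities never give rise to edges downstream.
#'
#' @param m a \linkS4class{TernaryExpressionMatrix} with >= 3 conditions.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{"pcc"}.
#' @export
pearsonAll <- function(m) {
  v <- ternaryValues(m)
  if (ncol(v) < 3) stop("at least 3 conditions required")
  storage.mode(v) <- "double"
  cc <- suppressWarnings(cor(t(v)))
  const <- apply(v, 1, function(r) var(r) == 0)
  if (any(const)) {
    message(sum(const), " zero-variance gene(s): PCC undefined (NA)")
    cc[const, ] <- NA_real_
    cc[, const] <- NA_real_
  }
  # guard against floating drift outside [-1, 1]
  cc[] <- pmin(pmax(cc, -1), 1)
  diag(cc) <- NA_real_
  SimilarityMatrix(cc, "pcc")
}

#' Fixed-threshold PCC network
#'
#' An edge joins two genes iff their (signed) correlation is >= the
#' threshold.  Strong negative correlation never makes an edge under
#' the default signed rule.  Every gene is retained as a node, so the
#' node count is constant regardless of the threshold.
#'
#' @param s a \linkS4class{SimilarityMatrix} of kind \code{"pcc"}.
#' @param t threshold in (0, 1]; the reference analysis uses 0.9.
#' @param absolute use |PCC| instead of signed PCC (off by default).
#' @return a \linkS4class{CoexpressionNetwork} with edge weights equal
#'   to the correlations.
#' @export
pccThresholdNetwork <- function(s, t = 0.9, absolute = FALSE) {
  stopifnot(identical(simKind(s), "pcc"))
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t > 1)
    stop("threshold must lie in (0, 1]")
  w <- simWeights(s)
  cmp <- if (absolute) abs(w) else w
  sel <- which(upper.tri(w) & !is.na(cmp) & cmp >= t, arr.ind = TRUE)
  ids <- geneIds(s)
  CoexpressionNetwork(ids,
                      cbind(ids[sel[, 1]], ids[sel[, 2]]),
                      weights = w[sel])
}

# k-list of one gene: indices of the k-1 top partners plus all partners
# tied (tol 1e-12) with the k-th largest similarity.  NA-similarity
# partners rank below everything and never enter the list.
.kList <- function(row, k, tol = 1e-12) {
  ok <- which(!is.na(row))
  if (length(ok) == 0) return(integer(0))
  vals <- row[ok]
  if (length(ok) <= k) return(ok)
  vk <- sort(vals, decreasing = TRUE)[k]
  ok[vals >= vk - tol]
}

#' Mutual k-nearest-neighbour network
#'
#' Modified mKNN rule: each gene's k-list holds its k-1 highest-PCC
#' partners plus \emph{all} genes sharing the k-th (smallest listed)
#' PCC value, on the grounds that equal correlations are equally valid
#' neighbours.  An edge requires mutual membership: u in k-list(v) and
#' v in k-list(u).  Genes with undefined PCC (zero variance) never form
#' edges; all genes are retained as nodes.
#'
#' @param s a \linkS4class{SimilarityMatrix} of kind \code{"pcc"}
#'   (ranking is on signed values; see \code{absolute}).
#' @param k positive integer < number of genes.
#' @param absolute rank by |PCC| instead of signed PCC.
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
mknnNetwork <- function(s, k, absolute = FALSE) {
  stopifnot(identical(simKind(s), "pcc"))
  w <- simWeights(s)
  n <- nrow(w)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= n)
    stop("k must satisfy 1 <= k < number of genes")
  if (absolute) w <- abs(w)
  diag(w) <- NA_real_
  klists <- lapply(seq_len(n), function(i) .kList(w[i, ], k))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in klists[[i]]) {
      if (j > i && i %in% klists[[j]])
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  ids <- geneIds(s)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    CoexpressionNetwork(ids, cbind(ids[em[, 1]], ids[em[, 2]]),
                        weights = simWeights(s)[em])
  } else {
    CoexpressionNetwork(ids)
  }
}
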