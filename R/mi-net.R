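## Non-linear co-expression inference: Kraskov k-nearest-neighbour
## mutual information over jittered ternary profiles, then ARACNE
## (data-processing-inequality), CLR and MRNET post-processing, and
## max-fraction thresholding into networks.

#' Mutual-information configuration
#'
#' @param k_neighbors Kraskov estimator neighbourhood size (default 3).
#' @param jitter_sd scale of the i.i.d. Gaussian jitter added to break
#'   the massive ties of ternary data (default 1e-12).
#' @param seed RNG seed for the jitter.
#' @param dpi_mode ARACNE pruning mode, \code{"additive"} or
#'   \code{"multiplicative"}.
#' @param dpi_tolerance epsilon >= 0 (additive) or tau in (0, 1]
#'   (multiplicative); defaults give strict DPI.
#' @param threshold_fraction fraction of the maximum weight used as the
#'   edge threshold (the reference analysis uses 0.8 and 0.9).
#' @return list with class \code{"MiConfig"}.
#' @export
miConfig <- function(k_neighbors = 3L, jitter_sd = 1e-12, seed = 1L,
                     dpi_mode = c("multiplicative", "additive"),
                     dpi_tolerance = NULL,
                     threshold_fraction = 0.8) {
  dpi_mode <- match.arg(dpi_mode)
  if (is.null(dpi_tolerance))
    dpi_tolerance <- if (dpi_mode == "additive") 0 else 1
  stopifnot(k_neighbors >= 1, jitter_sd > 0,
            threshold_fraction > 0, threshold_fraction <= 1)
  if (dpi_mode == "additive" && dpi_tolerance < 0)
    stop("additive tolerance must be >= 0")
  if (dpi_mode == "multiplicative" &&
      (dpi_tolerance <= 0 || dpi_tolerance > 1))
    stop("multiplicative tolerance must lie in (0, 1]")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 jitter_sd = jitter_sd, seed = seed,
                 dpi_mode = dpi_mode, dpi_tolerance = dpi_tolerance,
                 threshold_fraction = threshold_fraction),
            class = "MiConfig")
}

#' Kraskov mutual information of one pair
#'
#' First Kraskov estimator: I(X,Y) = psi(k) + psi(N)
#' - <psi(nx+1) + psi(ny+1)>, with the k-th neighbour distance taken in
#' the max-norm and nx, ny counting points strictly within that
#' distance along each marginal.  Estimates can be slightly negative;
#' they are reported raw.
#'
#' @param x,y numeric vectors of equal length N (ties should be broken
#'   by jitter before calling).
#' @param k neighbourhood size, k < N.
#' @return MI estimate in nats.
#' @export
kraskovPairMI <- function(x, y, k = 3L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (k >= n) stop("k_neighbors must be smaller than the sample size")
  acc <- 0
  for (i in seq_len(n)) {
    dx <- abs(x - x[i])
    dy <- abs(y - y[i])
    dz <- pmax(dx, dy)
    dz[i] <- Inf
    eps <- sort.int(dz, partial = k)[k]
    nx <- sum(dx < eps) - 1L    # self always counted (dx[i] = 0)
    ny <- sum(dy < eps) - 1L
    acc <- acc + digamma(nx + 1L) + digamma(ny + 1L)
  }
  digamma(k) + digamma(n) - acc / n
}

#' All-pairs Kraskov mutual information
#'
#' Adds seeded i.i.d. Gaussian jitter of scale \code{cfg$jitter_sd} to
#' every cell (ternary values are massively tied, which the k-NN
#' estimator cannot tolerate), then estimates MI for every gene pair.
#'
#' @param m a \linkS4class{TernaryExpressionMatrix} with >= 3 conditions.
#' @param cfg a \code{\link{miConfig}}.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{"mi"}.
#' @export
kraskovMiAll <- function(m, cfg = miConfig()) {
  v <- ternaryValues(m)
  if (ncol(v) < 3) stop("at least 3 conditions required")
  storage.mode(v) <- "double"
  v <- withSeed(cfg$seed,
                v + matrix(rnorm(length(v), sd = cfg$jitter_sd),
                           nrow(v), ncol(v)))
  n <- nrow(v)
  w <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      w[i, j] <- w[j, i] <- kraskovPairMI(v[i, ], v[j, ], cfg$k_neighbors)
    }
  }
  SimilarityMatrix(w, "mi")
}

#' ARACNE data-processing-inequality pruning
#'
#' For every unordered gene triple (i, j, k) the weakest edge is marked
#' for removal: (i, j) goes when MI_ij < min(MI_ik, MI_jk) - epsilon
#' (additive) or MI_ij < tau * min(MI_ik, MI_jk) (multiplicative).
#' All removal decisions are taken on the input matrix and applied
#' together afterwards, so triple scan order is irrelevant.  Removed
#' entries are set to 0.
#'
#' @param s a symmetric \linkS4class{SimilarityMatrix} of kind \code{"mi"}.
#' @param mode \code{"additive"} or \code{"multiplicative"}.
#' @param tolerance epsilon >= 0 (additive) or tau in (0, 1]
#'   (multiplicative).
#' @return a pruned \linkS4class{SimilarityMatrix} of kind \code{"mi"}.
#' @export
aracnePrune <- function(s, mode = c("multiplicative", "additive"),
                        tolerance = NULL) {
  mode <- match.arg(mode)
  if (is.null(tolerance)) tolerance <- if (mode == "additive") 0 else 1
  if (mode == "additive" && tolerance < 0)
    stop("additive tolerance must be >= 0")
  if (mode == "multiplicative" && (tolerance <= 0 || tolerance > 1))
    stop("multiplicative tolerance must lie in (0, 1]")
  w <- simWeights(s)
  n <- nrow(w)
  ww <- w
  diag(ww) <- -Inf
  # bound[i,j] = max over k != i,j of min(w[i,k], w[j,k]); the -Inf
  # diagonal voids the k == i and k == j terms.
  bound <- matrix(-Inf, n, n)
  for (k in seq_len(n)) {
    a <- ww[, k]
    bound <- pmax(bound, outer(a, a, pmin))
  }
  remove <- if (mode == "additive") w < bound - tolerance
            else w < tolerance * bound
  out <- w
  out[remove] <- 0
  diag(out) <- 0
  SimilarityMatrix(out, "mi")
}

#' Context-likelihood-of-relatedness transform
#'
#' Per-gene background correction of the MI matrix: each gene's
#' off-diagonal MI row yields a mean and SD; z_i(j) = max(0,
#' (MI_ij - mu_i) / sigma_i); the pair score is sqrt(z_i(j)^2 +
#' z_j(i)^2).  A zero-SD row contributes zeros (logged), not an error.
#'
#' @param s a symmetric \linkS4class{SimilarityMatrix} of kind
#'   \code{"mi"} over >= 3 genes.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{"clr_score"}.
#' @export
clrTransform <- function(s) {
  w <- simWeights(s)
  n <- nrow(w)
  if (n < 3) stop("CLR needs at least 3 genes")
  wo <- w
  diag(wo) <- NA_real_
  mu <- rowMeans(wo, na.rm = TRUE)
  sg <- apply(wo, 1L, sd, na.rm = TRUE)
  zero <- sg == 0 | is.na(sg)
  if (any(zero))
    message(sum(zero), " gene(s) with zero MI spread: z contributions set to 0")
  z <- (wo - mu) / ifelse(zero, Inf, sg)
  z[z < 0 | is.na(z)] <- 0
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  SimilarityMatrix(out, "clr_score")
}

#' MRNET maximum-relevance-minimum-redundancy network scores
#'
#' For each target gene Y, forward selection over candidates X by the
#' MRMR score s_j = MI(X_j, Y) - mean over already-selected S of
#' MI(X_j, X_k); selection continues while the best score is positive.
#' The output weight of a pair is the larger of its two directional
#' scores at selection time; pairs never selected score 0.
#'
#' @param s a symmetric \linkS4class{SimilarityMatrix} of kind \code{"mi"}.
#' @return a \linkS4class{SimilarityMatrix} of kind \code{"mrnet_score"}
#'   (non-negative everywhere).
#' @export
mrnetBuild <- function(s) {
  w <- simWeights(s)
  n <- nrow(w)
  out <- matrix(0, n, n, dimnames = dimnames(w))
  for (y in seq_len(n)) {
    cand <- setdiff(seq_len(n), y)
    rel <- w[cand, y]
    red <- rep(0, length(cand))   # running sum of MI to selected genes
    picked <- logical(length(cand))
    nsel <- 0L
    repeat {
      score <- rel - if (nsel) red / nsel else 0
      score[picked] <- -Inf
      b <- which.max(score)
      if (!is.finite(score[b]) || score[b] <= 0) break
      g <- cand[b]
      out[g, y] <- max(out[g, y], score[b])
      picked[b] <- TRUE
      nsel <- nsel + 1L
      red <- red + w[cand, g]
    }
  }
  out <- pmax(out, t(out))
  diag(out) <- 0
  SimilarityMatrix(out, "mrnet_score")
}

#' Max-fraction threshold network
#'
#' The edge threshold is \code{fraction} times the maximum off-diagonal
#' weight; an edge joins genes whose weight is >= the threshold.
#' Isolated genes are dropped, so MI-derived networks generally have
#' fewer nodes than the input gene universe (unlike PCC networks, which
#' keep every gene).
#'
#' @param s a \linkS4class{SimilarityMatrix} (any kind).
#' @param fraction fraction of the maximum in (0, 1].
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
fractionThresholdNetwork <- function(s, fraction = 0.8) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  w <- simWeights(s)
  off <- w
  diag(off) <- NA_real_
  mx <- max(off, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("no edges at any threshold: all weights are zero or negative")
  thr <- fraction * mx
  sel <- which(upper.tri(off) & !is.na(off) & off >= thr, arr.ind = TRUE)
  ids <- geneIds(s)
  keep <- sort(unique(c(sel[, 1], sel[, 2])))
  CoexpressionNetwork(ids[keep],
                      cbind(ids[sel[, 1]], ids[sel[, 2]]),
                      weights = off[sel])
}
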