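## Seeded generators for all synthetic fixtures: ternary expression
## matrices with planted co-expressed gene blocks, permutation nulls,
## and promoter sets with planted elements.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded helpers never perturb
#' surrounding randomness.  A \code{NULL} seed evaluates \code{expr}
#' unchanged.
#'
#' @param seed integer seed, or \code{NULL} for no seeding.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Planted co-expression truth
#'
#' Describes the ground truth behind a synthetic ternary expression
#' matrix: which genes belong to which module, the ternary template
#' pattern each module follows across conditions, and the per-cell
#' corruption probability.
#'
#' @param module_sizes integer vector, one entry per planted module.
#' @param n_conditions number of conditions the templates span.
#' @param flip_prob per-cell probability of flipping a value to a random
#'   other ternary value; must be < 0.5 (above that the planted
#'   structure is unrecoverable by design).
#' @param templates optional list of ternary vectors (one per module,
#'   each of length \code{n_conditions}); drawn at random when omitted.
#' @param template_freqs sampling frequencies of (-1, 0, +1) for random
#'   templates.
#' @param seed RNG seed for random template draws.
#' @return list with class \code{"PlantedExpressionTruth"}: components
#'   \code{module_assignments} (gene index -> module, 0 = background),
#'   \code{template_patterns}, \code{flip_prob}.
#' @export
plantedExpressionTruth <- function(module_sizes, n_conditions,
                                   flip_prob = 0.1, templates = NULL,
                                   template_freqs = c(0.2, 0.6, 0.2),
                                   seed = NULL) {
  stopifnot(all(module_sizes >= 1), n_conditions >= 2)
  if (flip_prob >= 0.5)
    stop("flip_prob must be < 0.5: planted structure unrecoverable")
  if (is.null(templates)) {
    templates <- withSeed(seed, lapply(seq_along(module_sizes), function(i)
      sample(c(-1L, 0L, 1L), n_conditions, replace = TRUE,
             prob = template_freqs)))
  }
  stopifnot(length(templates) == length(module_sizes),
            all(lengths(templates) == n_conditions))
  assign <- rep.int(seq_along(module_sizes), module_sizes)
  structure(list(module_assignments = assign,
                 template_patterns = lapply(templates, as.integer),
                 flip_prob = flip_prob,
                 n_conditions = n_conditions),
            class = "PlantedExpressionTruth")
}

#' Generate a ternary expression matrix with planted modules
#'
#' Genes assigned to module m copy the module's template pattern; each
#' cell is independently flipped to a uniformly chosen different
#' ternary value with probability \code{truth$flip_prob}.  The
#' remaining (background) genes get i.i.d. ternary cells.
#'
#' @param n_genes total genes (>= number of planted genes).
#' @param n_conditions number of conditions (must match the truth).
#' @param truth a \code{\link{plantedExpressionTruth}} object.
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @param background_freqs i.i.d. frequencies of (-1, 0, +1) for
#'   background genes.
#' @return a \linkS4class{TernaryExpressionMatrix}; planted genes come
#'   first, named \code{gene0001 ...}; the truth module index of every
#'   gene is stored in \code{metadata$module_assignments}.
#' @export
synthExpression <- function(n_genes, n_conditions, truth, seed,
                            background_freqs = c(0.15, 0.7, 0.15)) {
  stopifnot(inherits(truth, "PlantedExpressionTruth"),
            n_conditions == truth$n_conditions)
  n_planted <- length(truth$module_assignments)
  if (n_genes < n_planted)
    stop("n_genes smaller than the number of planted genes")
  vals <- c(-1L, 0L, 1L)
  withSeed(seed, {
    v <- matrix(0L, n_genes, n_conditions)
    for (i in seq_len(n_planted)) {
      row <- truth$template_patterns[[truth$module_assignments[i]]]
      flip <- runif(n_conditions) < truth$flip_prob
      if (any(flip))
        row[flip] <- vapply(row[flip], function(x)
          sample(setdiff(vals, x), 1L), integer(1))
      v[i, ] <- row
    }
    if (n_genes > n_planted) {
      nb <- n_genes - n_planted
      v[(n_planted + 1):n_genes, ] <-
        sample(vals, nb * n_conditions, replace = TRUE,
               prob = background_freqs)
    }
    dimnames(v) <- list(sprintf("gene%04d", seq_len(n_genes)),
                        sprintf("cond%03d", seq_len(n_conditions)))
    TernaryExpressionMatrix(v, metadata = list(
      module_assignments = c(truth$module_assignments,
                             rep(0L, n_genes - n_planted)),
      flip_prob = truth$flip_prob, seed = seed))
  })
}

#' Randomize a ternary matrix (null model)
#'
#' Re-assigns expression values at random to destroy all co-expression
#' structure.  The default mode permutes each condition column across
#' genes, preserving the per-condition up/down/no-change counts (the
#' stricter null); \code{"row"} permutes within genes, \code{"global"}
#' permutes the whole matrix, \code{"iid"} resamples cells i.i.d. from
#' the matrix-wide value frequencies.
#'
#' @param m a \linkS4class{TernaryExpressionMatrix}.
#' @param seed RNG seed.
#' @param mode one of \code{"column"}, \code{"row"}, \code{"global"},
#'   \code{"iid"}.
#' @return a \linkS4class{TernaryExpressionMatrix} of identical shape.
#' @export
randomizeExpression <- function(m, seed,
                                mode = c("column", "row", "global", "iid")) {
  mode <- match.arg(mode)
  v <- ternaryValues(m)
  withSeed(seed, {
    r <- switch(mode,
      column = apply(v, 2, sample),
      row    = t(apply(v, 1, sample)),
      global = matrix(sample(v), nrow(v), ncol(v)),
      iid    = matrix(sample(c(-1L, 0L, 1L), length(v), replace = TRUE,
                             prob = tabulate(v + 2L, 3L) / length(v)),
                      nrow(v), ncol(v)))
    dimnames(r) <- dimnames(v)
    storage.mode(r) <- "integer"
    TernaryExpressionMatrix(r, metadata = list(null_mode = mode, seed = seed))
  })
}

#' Planted promoter element truth
#'
#' @param motif DNA string to plant.  Alignment-driven candidate
#'   discovery needs a conserved block longer than the aligner's word
#'   size, so the default planting unit is a multi-k-mer element
#'   (typically ~24 nt); its constituent 6-mers are the recoverable
#'   units.  Must itself pass the homopolymer rule (no run of 5+
#'   identical letters).
#' @param cluster_rate expected planted copies per cluster promoter
#'   (Poisson).
#' @param background_rate expected planted copies per background
#'   promoter (Poisson).
#' @return list with class \code{"PlantedMotifTruth"}.
#' @export
plantedMotifTruth <- function(motif, cluster_rate, background_rate = 0) {
  motif <- toupper(motif)
  stopifnot(cluster_rate >= 0, background_rate >= 0,
            grepl("^[ACGT]+$", motif))
  if (max(rle(strsplit(motif, "")[[1]])$lengths) > 4)
    stop("motif fails the homopolymer rule (run of 5+ identical letters)")
  structure(list(motif = motif, cluster_rate = cluster_rate,
                 background_rate = background_rate),
            class = "PlantedMotifTruth")
}

# Insert ncopy non-overlapping copies of motif into one sequence (char
# vector); returns list(seq, starts).  Errors when copies cannot fit.
.plantCopies <- function(chars, motif, ncopy) {
  L <- length(chars)
  w <- nchar(motif)
  if (ncopy * w > L)
    stop("requested insertions exceed promoter capacity")
  mv <- strsplit(motif, "")[[1]]
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < ncopy) {
    s <- sample.int(L - w + 1L, 1L)
    if (!any(abs(s - starts) < w)) {
      starts <- c(starts, s)
    } else {
      tries <- tries + 1L
      if (tries > 1000L) stop("requested insertions exceed promoter capacity")
    }
  }
  for (s in starts) chars[s:(s + w - 1L)] <- mv
  list(seq = chars, starts = sort(starts))
}

#' Generate promoter sets with a planted element
#'
#' Background composition is i.i.d. uniform over ACGT.  Per-promoter
#' copy numbers of the planted element are Poisson with mean
#' \code{truth$cluster_rate} in the cluster set and
#' \code{truth$background_rate} in the background set; copies land at
#' uniform random non-overlapping positions.  True insertion positions
#' are recorded for evaluation.
#'
#' @param n_cluster,n_background set sizes.
#' @param length promoter length in bp (default 1000, the nominal
#'   upstream window).
#' @param truth a \code{\link{plantedMotifTruth}}.
#' @param seed RNG seed.
#' @return list with components \code{cluster} and \code{background}
#'   (\linkS4class{PromoterSet}s) and \code{positions} (per-set lists of
#'   1-based insertion starts).
#' @export
synthPromoters <- function(n_cluster, n_background, length = 1000,
                           truth, seed) {
  stopifnot(inherits(truth, "PlantedMotifTruth"),
            length >= nchar(truth$motif))
  withSeed(seed, {
    gen <- function(n, rate, prefix) {
      seqs <- character(n)
      pos <- vector("list", n)
      for (i in seq_len(n)) {
        chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
        nc <- rpois(1L, rate)
        if (nc > 0) {
          pl <- .plantCopies(chars, truth$motif, nc)
          chars <- pl$seq
          pos[[i]] <- pl$starts
        } else pos[[i]] <- integer(0)
        seqs[i] <- paste(chars, collapse = "")
      }
      names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
      names(pos) <- names(seqs)
      list(ps = PromoterSet(seqs), pos = pos)
    }
    cl <- gen(n_cluster, truth$cluster_rate, "clust")
    bg <- gen(n_background, truth$background_rate, "bg")
    list(cluster = cl$ps, background = bg$ps,
         positions = list(cluster = cl$pos, background = bg$pos))
  })
}
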