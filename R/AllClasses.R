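#' @import methods
#' @importFrom stats cor sd var setNames rnorm runif rpois quantile coef lm pt
#' @importFrom utils head read.delim write.table
NULL

setOldClass("igraph")

#' Ternary differential-expression matrix
#'
#' Genes x conditions matrix of differential-expression calls coded
#' +1 (up-regulated), -1 (down-regulated), 0 (no change).  This is the
#' common input of all network-inference functions in the package.
#'
#' @slot values integer matrix with unique gene row names and unique
#'   condition column names; every cell is exactly -1, 0 or +1.
#' @slot metadata list of free-form provenance entries (e.g. the
#'   condition granularity of the source tables).
#' @export
setClass("TernaryExpressionMatrix",
  representation(values = "matrix", metadata = "list"),
  prototype(metadata = list()))

setValidity("TernaryExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric/integer matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry gene row names and condition column names")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate gene ids")
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate condition ids")
  if (ncol(v) < 2L)
    msg <- c(msg, "at least 2 conditions required")
  if (is.numeric(v) && !all(v %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "all cells must be -1, 0 or +1")
  if (length(msg)) msg else TRUE
})

#' Construct a TernaryExpressionMatrix
#'
#' @param values numeric matrix of -1/0/+1 calls with gene row names and
#'   condition column names.
#' @param metadata optional list of provenance entries.
#' @return a \linkS4class{TernaryExpressionMatrix}.
#' @examples
#' m <- matrix(c(1L, -1L, 0L, 1L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' TernaryExpressionMatrix(m)
#' @export
TernaryExpressionMatrix <- function(values, metadata = list()) {
  storage.mode(values) <- "integer"
  new("TernaryExpressionMatrix", values = values, metadata = metadata)
}

#' Gene-gene similarity matrix
#'
#' Symmetric gene x gene weight matrix tagged with the statistic it
#' holds: Pearson correlation (\code{pcc}), mutual information
#' (\code{mi}), CLR z-score combination (\code{clr_score}) or MRNET
#' selection score (\code{mrnet_score}).  The diagonal is ignored by all
#' consumers.  \code{NA} entries mark undefined values (e.g. PCC of a
#' zero-variance gene) and never give rise to edges.
#'
#' @slot weights symmetric numeric matrix with identical row/column
#'   gene names.
#' @slot kind one of \code{"pcc"}, \code{"mi"}, \code{"clr_score"},
#'   \code{"mrnet_score"}.
#' @export
setClass("SimilarityMatrix",
  representation(weights = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w))
    msg <- c(msg, "'weights' must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    msg <- c(msg, "row and column gene ids must be identical")
  off <- w
  diag(off) <- 0
  if (max(abs(off - t(off)), na.rm = TRUE) > 1e-12)
    msg <- c(msg, "'weights' must be symmetric to within 1e-12")
  if (!object@kind %in% c("pcc", "mi", "clr_score", "mrnet_score"))
    msg <- c(msg, "unknown 'kind'")
  if (identical(object@kind, "pcc")) {
    rng <- range(off, na.rm = TRUE)
    if (rng[1] < -1 - 1e-12 || rng[2] > 1 + 1e-12)
      msg <- c(msg, "pcc weights must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param weights symmetric numeric matrix with gene dimnames.
#' @param kind statistic tag; see \linkS4class{SimilarityMatrix}.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
SimilarityMatrix <- function(weights, kind) {
  new("SimilarityMatrix", weights = weights, kind = kind)
}

#' Undirected gene co-expression network
#'
#' A simple (no loops, no multi-edges) undirected graph over gene ids,
#' backed by an \pkg{igraph} object.  Edge weights, when present, are
#' the similarity values that created the edges.
#'
#' @slot graph an \pkg{igraph} undirected simple graph with a \code{name}
#'   vertex attribute.
#' @export
setClass("CoexpressionNetwork", representation(graph = "igraph"))

setValidity("CoexpressionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g))
    msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g)))
    msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g)))
    msg <- c(msg, "duplicate edges are not allowed")
  if (is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named")
  if (length(msg)) msg else TRUE
})

#' Construct a CoexpressionNetwork
#'
#' @param nodes character vector of gene ids (isolated nodes allowed).
#' @param edges two-column character matrix/data.frame of edge endpoints
#'   (may be empty).
#' @param weights optional numeric edge weights parallel to \code{edges}.
#' @return a \linkS4class{CoexpressionNetwork}.
#' @examples
#' CoexpressionNetwork(c("a", "b", "c"), cbind("a", "b"))
#' @export
CoexpressionNetwork <- function(nodes, edges = NULL, weights = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    em <- as.matrix(edges)
    if (ncol(em) < 2) stop("'edges' needs two columns")
    bad <- !(em[, 1] %in% nodes) | !(em[, 2] %in% nodes)
    if (any(bad)) stop("edge endpoint not in 'nodes'")
    g <- igraph::add_edges(g, rbind(em[, 1], em[, 2]))
    if (!is.null(weights)) igraph::E(g)$weight <- as.numeric(weights)
  }
  new("CoexpressionNetwork", graph = g)
}

#' Wrap an igraph object as a CoexpressionNetwork
#'
#' @param g an undirected simple \pkg{igraph} graph with named vertices.
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
asCoexpressionNetwork <- function(g) new("CoexpressionNetwork", graph = g)

#' Disjoint gene modules
#'
#' Result of FAG-EC or MCL clustering: a list of pairwise-disjoint gene
#' sets that passed the minimum-size filter, together with the
#' parameters that produced them.
#'
#' @slot modules named list of character vectors (gene ids), sorted by
#'   decreasing size.
#' @slot parameters list recording algorithm tag and tuning values
#'   (lambda or inflation, min_size).
#' @export
setClass("ModuleSet", representation(modules = "list", parameters = "list"))

setValidity("ModuleSet", function(object) {
  mods <- object@modules
  msg <- character()
  all_genes <- unlist(mods, use.names = FALSE)
  if (anyDuplicated(all_genes))
    msg <- c(msg, "modules must be pairwise disjoint")
  ms <- object@parameters$min_size
  if (!is.null(ms) && length(mods) && any(lengths(mods) < ms))
    msg <- c(msg, "module below min_size")
  if (length(msg)) msg else TRUE
})

#' Construct a ModuleSet
#'
#' @param modules list of character vectors of gene ids.
#' @param parameters list of algorithm parameters.
#' @return a \linkS4class{ModuleSet}.
#' @export
ModuleSet <- function(modules, parameters = list()) {
  if (length(modules)) {
    modules <- modules[order(-lengths(modules))]
    names(modules) <- sprintf("M%d", seq_along(modules))
  }
  new("ModuleSet", modules = modules, parameters = parameters)
}

#' Promoter sequence set
#'
#' Gene id -> upstream sequence map (nominally 1000 bp each) over the
#' alphabet ACGTN, stored as a \pkg{Biostrings} \code{DNAStringSet}.
#'
#' @slot sequences a named \code{DNAStringSet}; names are unique gene ids.
#' @export
setClass("PromoterSet", representation(sequences = "DNAStringSet"))

setValidity("PromoterSet", function(object) {
  s <- object@sequences
  msg <- character()
  if (length(s) && (is.null(names(s)) || anyDuplicated(names(s))))
    msg <- c(msg, "sequences must carry unique gene ids")
  if (length(s)) {
    freq <- Biostrings::alphabetFrequency(s, collapse = TRUE)
    extra <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
    if (extra > 0)
      msg <- c(msg, "sequences may contain only A, C, G, T, N")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PromoterSet
#'
#' Lowercase input is uppercased; any character outside ACGTN is an
#' error naming the offending record.
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @return a \linkS4class{PromoterSet}.
#' @examples
#' PromoterSet(c(g1 = "acgtACGT", g2 = "TTTTNNNN"))
#' @export
PromoterSet <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- toupper(sequences)
    bad <- grepl("[^ACGTN]", sequences)
    if (any(bad))
      stop("non-ACGTN characters in record(s): ",
           paste(names(sequences)[bad], collapse = ", "))
    sequences <- Biostrings::DNAStringSet(sequences)
  } else {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  new("PromoterSet", sequences = sequences)
}

#' Candidate k-mer set
#'
#' 6-mers extracted from aligned promoter spans, each with the number
#' of supporting alignment hits.  Every member passes the homopolymer
#' rule (no run of 5 or more identical letters).
#'
#' @slot kmers character vector of length-6 ACGT strings.
#' @slot support named integer vector of supporting-hit counts,
#'   parallel to \code{kmers}.
#' @export
setClass("KmerCandidateSet",
  representation(kmers = "character", support = "integer"))

setValidity("KmerCandidateSet", function(object) {
  k <- object@kmers
  msg <- character()
  if (length(k) != length(object@support))
    msg <- c(msg, "'support' must be parallel to 'kmers'")
  if (length(k)) {
    if (any(nchar(k) != 6)) msg <- c(msg, "all k-mers must have length 6")
    if (any(grepl("[^ACGT]", k))) msg <- c(msg, "k-mers must be over ACGT")
    if (any(grepl("A{5}|C{5}|G{5}|T{5}", k)))
      msg <- c(msg, "k-mer with a homopolymer run of 5+")
    if (anyDuplicated(k)) msg <- c(msg, "duplicate k-mers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KmerCandidateSet
#'
#' @param kmers character vector of length-6 ACGT strings.
#' @param support integer vector of supporting-hit counts (default 1 each).
#' @return a \linkS4class{KmerCandidateSet}.
#' @export
KmerCandidateSet <- function(kmers, support = rep(1L, length(kmers))) {
  new("KmerCandidateSet", kmers = as.character(kmers),
      support = setNames(as.integer(support), kmers))
}

#' Known cis-regulatory element list
#'
#' Plain list of experimentally known element sequences (ACGT, length
#' >= 4) used for precision evaluation of discovered k-mers.
#'
#' @slot elements character vector of DNA strings.
#' @export
setClass("KnownElementList", representation(elements = "character"))

setValidity("KnownElementList", function(object) {
  e <- object@elements
  msg <- character()
  if (!length(e)) msg <- c(msg, "element list must be non-empty")
  if (length(e) && any(nchar(e) < 4))
    msg <- c(msg, "elements must be at least 4 nt long")
  if (length(e) && any(grepl("[^ACGT]", e)))
    msg <- c(msg, "elements must be over the ACGT alphabet")
  if (length(msg)) msg else TRUE
})

#' Construct a KnownElementList
#'
#' @param elements character vector of ACGT strings (length >= 4).
#' @return a \linkS4class{KnownElementList}.
#' @export
KnownElementList <- function(elements) {
  new("KnownElementList", elements = toupper(as.character(elements)))
}
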