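#' @describeIn TernaryExpressionMatrix-class gene identifiers
#' @param object,x an object of the documented class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @describeIn TernaryExpressionMatrix-class condition identifiers
#' @export
setGeneric("conditionIds", function(object) standardGeneric("conditionIds"))

#' @describeIn TernaryExpressionMatrix-class the underlying -1/0/+1 matrix
#' @export
setGeneric("ternaryValues", function(object) standardGeneric("ternaryValues"))

setMethod("geneIds", "TernaryExpressionMatrix",
          function(object) rownames(object@values))
setMethod("conditionIds", "TernaryExpressionMatrix",
          function(object) colnames(object@values))
setMethod("ternaryValues", "TernaryExpressionMatrix",
          function(object) object@values)

setMethod("show", "TernaryExpressionMatrix", function(object) {
  v <- object@values
  cat("TernaryExpressionMatrix:", nrow(v), "genes x", ncol(v), "conditions\n")
  cat("  up calls:", sum(v == 1L), " down calls:", sum(v == -1L), "\n")
})

#' @describeIn SimilarityMatrix-class the symmetric weight matrix
#' @export
setGeneric("simWeights", function(object) standardGeneric("simWeights"))

#' @describeIn SimilarityMatrix-class the statistic tag
#' @export
setGeneric("simKind", function(object) standardGeneric("simKind"))

setMethod("simWeights", "SimilarityMatrix", function(object) object@weights)
setMethod("simKind", "SimilarityMatrix", function(object) object@kind)
setMethod("geneIds", "SimilarityMatrix",
          function(object) rownames(object@weights))

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix (", object@kind, "): ",
      nrow(object@weights), " genes\n", sep = "")
})

#' @describeIn CoexpressionNetwork-class node (gene) ids
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @describeIn CoexpressionNetwork-class two-column character matrix of edges
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @describeIn CoexpressionNetwork-class number of nodes
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @describeIn CoexpressionNetwork-class number of edges
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @describeIn CoexpressionNetwork-class underlying igraph object
#' @export
setGeneric("asIgraph", function(object) standardGeneric("asIgraph"))

setMethod("networkNodes", "CoexpressionNetwork",
          function(object) igraph::V(object@graph)$name)
setMethod("networkEdges", "CoexpressionNetwork", function(object) {
  e <- igraph::as_edgelist(object@graph, names = TRUE)
  colnames(e) <- c("node1", "node2")
  e
})
setMethod("nNodes", "CoexpressionNetwork",
          function(object) igraph::vcount(object@graph))
setMethod("nEdges", "CoexpressionNetwork",
          function(object) igraph::ecount(object@graph))
setMethod("asIgraph", "CoexpressionNetwork", function(object) object@graph)

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", nNodes(object), "nodes,",
      nEdges(object), "edges\n")
})

#' @describeIn ModuleSet-class list of gene-id vectors
#' @export
setGeneric("moduleList", function(object) standardGeneric("moduleList"))

#' @describeIn ModuleSet-class per-module sizes
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @describeIn ModuleSet-class clustering parameters
#' @export
setGeneric("moduleParameters", function(object) standardGeneric("moduleParameters"))

setMethod("moduleList", "ModuleSet", function(object) object@modules)
setMethod("moduleSizes", "ModuleSet", function(object) lengths(object@modules))
setMethod("moduleParameters", "ModuleSet", function(object) object@parameters)
setMethod("length", "ModuleSet", function(x) length(x@modules))

setMethod("show", "ModuleSet", function(object) {
  sz <- lengths(object@modules)
  cat("ModuleSet:", length(sz), "modules")
  if (length(sz)) cat(" (sizes ", max(sz), " .. ", min(sz), ")", sep = "")
  cat("\n  parameters:",
      paste(names(object@parameters),
            vapply(object@parameters, function(p) paste(format(p), collapse = ","),
                   character(1)),
            sep = "=", collapse = ", "), "\n")
})

#' @describeIn PromoterSet-class the DNAStringSet of promoter sequences
#' @export
setGeneric("promoterSequences", function(object) standardGeneric("promoterSequences"))

#' @describeIn PromoterSet-class total sequence length (search-space term)
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))

setMethod("promoterSequences", "PromoterSet", function(object) object@sequences)
setMethod("totalLength", "PromoterSet",
          function(object) sum(Biostrings::width(object@sequences)))
setMethod("geneIds", "PromoterSet", function(object) names(object@sequences))
setMethod("length", "PromoterSet", function(x) length(x@sequences))

#' Subset a PromoterSet by gene id or index
#'
#' @param x a \linkS4class{PromoterSet}
#' @param i character gene ids or numeric indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "PromoterSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i) && !all(i %in% names(x@sequences)))
    stop("unknown gene id(s): ",
         paste(setdiff(i, names(x@sequences)), collapse = ", "))
  new("PromoterSet", sequences = x@sequences[i])
})

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet:", length(object@sequences), "promoters,",
      totalLength(object), "bp total\n")
})

#' @describeIn KmerCandidateSet-class the candidate 6-mers
#' @export
setGeneric("candidateKmers", function(object) standardGeneric("candidateKmers"))

#' @describeIn KmerCandidateSet-class supporting-hit counts per k-mer
#' @export
setGeneric("kmerSupport", function(object) standardGeneric("kmerSupport"))

setMethod("candidateKmers", "KmerCandidateSet", function(object) object@kmers)
setMethod("kmerSupport", "KmerCandidateSet", function(object) object@support)
setMethod("length", "KmerCandidateSet", function(x) length(x@kmers))

setMethod("show", "KmerCandidateSet", function(object) {
  cat("KmerCandidateSet:", length(object@kmers), "candidate 6-mers\n")
})

#' @describeIn KnownElementList-class the element strings
#' @export
setGeneric("elements", function(object) standardGeneric("elements"))
setMethod("elements", "KnownElementList", function(object) object@elements)
setMethod("length", "KnownElementList", function(x) length(x@elements))

setMethod("show", "KnownElementList", function(object) {
  cat("KnownElementList:", length(object@elements), "elements\n")
})
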