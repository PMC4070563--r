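#' Build a ternary matrix from per-condition up/down calls
#'
#' Core encoder: one row per (gene, condition, direction) call.  The
#' gene universe is the union of all genes ever listed; a gene gets +1
#' in a condition where it was called up, -1 where called down and 0
#' everywhere else.  A gene listed in both directions of the same
#' condition is a hard error; a gene duplicated within one direction is
#' counted once with a warning.
#'
#' @param calls data.frame with columns \code{gene_id}, \code{condition},
#'   \code{direction} (\code{"up"} or \code{"down"}).
#' @param condition_ids optional ordering/superset of condition labels;
#'   defaults to first-appearance order.
#' @return a \linkS4class{TernaryExpressionMatrix}; genes sorted
#'   lexicographically, conditions in \code{condition_ids} order.
#' @export
ternaryFromCalls <- function(calls, condition_ids = NULL) {
  stopifnot(all(c("gene_id", "condition", "direction") %in% names(calls)))
  if (nrow(calls) == 0) stop("no conditions")
  if (!all(calls$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  if (is.null(condition_ids))
    condition_ids <- unique(as.character(calls$condition))
  dup <- duplicated(calls[, c("gene_id", "condition", "direction")])
  if (any(dup)) {
    warning(sum(dup), " duplicated call(s) within a list; counted once")
    calls <- calls[!dup, ]
  }
  both <- duplicated(calls[, c("gene_id", "condition")])
  if (any(both)) {
    b <- calls[both, ][1, ]
    stop("gene '", b$gene_id, "' listed as both up and down in condition '",
         b$condition, "'")
  }
  genes <- sort(unique(as.character(calls$gene_id)))
  v <- matrix(0L, length(genes), length(condition_ids),
              dimnames = list(genes, condition_ids))
  sign <- ifelse(calls$direction == "up", 1L, -1L)
  v[cbind(match(calls$gene_id, genes),
          match(as.character(calls$condition), condition_ids))] <- sign
  TernaryExpressionMatrix(v, metadata = list(
    n_conditions = length(condition_ids),
    granularity = "as-supplied per-condition call tables"))
}

#' Read per-condition up/down call tables
#'
#' Each file is a two-column TSV (\code{gene_id}, \code{direction})
#' holding the differential-expression calls of one condition; the
#' condition label defaults to the file name without extension.
#'
#' @param files character vector of TSV paths.
#' @param condition_ids optional condition labels parallel to \code{files}.
#' @param header logical; do the files carry a header line?
#' @return a \linkS4class{TernaryExpressionMatrix}.
#' @export
readUpDownTables <- function(files, condition_ids = NULL, header = TRUE) {
  if (length(files) == 0) stop("no conditions")
  if (is.null(condition_ids))
    condition_ids <- sub("\\.[^.]*$", "", basename(files))
  tabs <- lapply(seq_along(files), function(i) {
    d <- read.delim(files[i], header = header, stringsAsFactors = FALSE,
                    col.names = c("gene_id", "direction"))
    if (ncol(d) < 2) stop("file '", files[i], "': expected two columns")
    d$condition <- condition_ids[i]
    d
  })
  ternaryFromCalls(do.call(rbind, tabs), condition_ids = condition_ids)
}

#' Write per-condition call tables
#'
#' Inverse of \code{\link{readUpDownTables}}: one TSV per condition with
#' the non-zero calls.  Round-tripping reproduces the matrix exactly up
#' to genes that are zero in every condition (which cannot be expressed
#' as calls).
#'
#' @param tem a \linkS4class{TernaryExpressionMatrix}.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writeConditionCalls <- function(tem, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- ternaryValues(tem)
  paths <- vapply(colnames(v), function(cc) {
    nz <- v[, cc] != 0L
    d <- data.frame(gene_id = rownames(v)[nz],
                    direction = ifelse(v[nz, cc] == 1L, "up", "down"))
    p <- file.path(dir, paste0(cc, ".tsv"))
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read promoter sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the gene id.
#' Lowercase bases are uppercased; characters outside ACGTN and
#' duplicate ids are errors.
#'
#' @param path FASTA file.
#' @return a \linkS4class{PromoterSet}.
#' @export
readFastaPromoters <- function(path) {
  s <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(s))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  PromoterSet(setNames(seqs, ids))
}

#' Read a known cis-regulatory element list
#'
#' Plain text, one ACGT string per line; blank lines and lines starting
#' with '#' are skipped.
#'
#' @param path text file.
#' @return a \linkS4class{KnownElementList}.
#' @export
readKnownElements <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  KnownElementList(x)
}

#' Write / read a co-expression network
#'
#' Plain tab-separated format with a node manifest so isolated nodes
#' survive a round trip: lines \code{N<TAB>id} list every node, lines
#' \code{E<TAB>u<TAB>v[<TAB>weight]} list edges.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path) {
  g <- asIgraph(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("N\t", igraph::V(g)$name), con)
  if (igraph::ecount(g) > 0) {
    e <- igraph::as_edgelist(g, names = TRUE)
    w <- igraph::E(g)$weight
    if (is.null(w))
      writeLines(paste("E", e[, 1], e[, 2], sep = "\t"), con)
    else
      writeLines(paste("E", e[, 1], e[, 2], format(w, digits = 15), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @param path file written by \code{writeNetwork}.
#' @return \code{readNetwork}: a \linkS4class{CoexpressionNetwork}.
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  nodes <- character()
  edges <- list()
  weights <- numeric()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] == "N" && length(f) == 2) {
      nodes <- c(nodes, f[2])
    } else if (f[1] == "E" && length(f) %in% c(3, 4)) {
      edges[[length(edges) + 1L]] <- f[2:3]
      if (length(f) == 4) weights <- c(weights, as.numeric(f[4]))
    } else {
      stop("malformed line ", i, " in '", path, "'")
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else NULL
  CoexpressionNetwork(nodes, em,
                      weights = if (length(weights) == length(edges) &&
                                    length(weights)) weights else NULL)
}
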