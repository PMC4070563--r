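## Promoter k-mer enrichment engine: alignment-driven shared 6-mer
## candidate generation, occurrence counting, POBO-style bootstrap
## enrichment with fold-ratio tiers, and precision evaluation against
## known cis-regulatory elements.

#' Homopolymer filter for candidate k-mers
#'
#' A k-mer is kept iff its longest run of identical letters is at most
#' 4 (6-mers such as AAAAAG are rejected, AAAAGT is kept).
#'
#' @param kmer character vector of length-6 ACGT strings.
#' @return logical vector: keep?
#' @export
homopolymerFilter <- function(kmer) {
  if (any(nchar(kmer) != 6) || any(grepl("[^ACGT]", kmer)))
    stop("k-mers must be length-6 ACGT strings")
  !grepl("A{5}|C{5}|G{5}|T{5}", kmer)
}

#' Count (overlapping) occurrences of a k-mer in one sequence
#'
#' Forward-strand occurrences are counted allowing overlap; with
#' \code{both_strands}, occurrences of the reverse complement are
#' added, except for palindromic k-mers (equal to their reverse
#' complement), which are counted on the forward strand only to avoid
#' double counting.
#'
#' @param kmer ACGT string.
#' @param seq character string or \code{DNAString}.
#' @param both_strands also count the reverse complement.
#' @return integer count.
#' @export
countOccurrences <- function(kmer, seq, both_strands = FALSE) {
  s <- Biostrings::DNAString(as.character(seq))
  p <- Biostrings::DNAString(kmer)
  n <- Biostrings::countPattern(p, s)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(p)
    if (as.character(rc) != kmer)
      n <- n + Biostrings::countPattern(rc, s)
  }
  as.integer(n)
}

# Per-promoter occurrence counts of one k-mer over a PromoterSet.
.promoterCounts <- function(kmer, ps, both_strands = FALSE) {
  seqs <- promoterSequences(ps)
  p <- Biostrings::DNAString(kmer)
  n <- Biostrings::vcountPattern(p, seqs)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(p)
    if (as.character(rc) != kmer)
      n <- n + Biostrings::vcountPattern(rc, seqs)
  }
  setNames(as.integer(n), names(seqs))
}

#' Shared k-mer candidates from all-vs-all promoter alignment
#'
#' Every promoter is used in turn as a query against the others; hits
#' passing the identity and E-value filters contribute all 6-mers of
#' their query-side aligned span (windows containing N are skipped).
#' The homopolymer filter is applied; provenance records the number of
#' supporting hits per k-mer.
#'
#' @param promoters a \linkS4class{PromoterSet} with >= 2 records.
#' @param min_identity minimum hit identity (default 0.75).
#' @param max_evalue maximum hit E-value (default 1e-4).
#' @param k candidate length (default 6).
#' @param word_size,match,mismatch,x_drop,K aligner parameters; see
#'   \code{\link{seedExtendAlign}}.
#' @return a \linkS4class{KmerCandidateSet}.
#' @export
sharedKmerCandidates <- function(promoters, min_identity = 0.75,
                                 max_evalue = 1e-4, k = 6,
                                 word_size = 7, match = 1, mismatch = -2,
                                 x_drop = 10, K = 0.46) {
  if (length(promoters) < 2) stop("need at least 2 promoters")
  seqs <- as.character(promoterSequences(promoters))
  ids <- sort(names(seqs))
  lambda <- karlinAltschulLambda(match, mismatch)
  n_db <- totalLength(promoters)
  idx <- lapply(seqs[ids], .seqIndex, word_size = word_size)
  collected <- list()
  for (qid in ids) {
    qi <- idx[[qid]]
    m_q <- length(qi$chars)
    for (sid in setdiff(ids, qid)) {
      h <- .alignPair(qi, idx[[sid]], word_size, match, mismatch, x_drop)
      if (is.null(h)) next
      # identity and E-value filters (search space: query x whole db)
      ev <- K * m_q * n_db * exp(-lambda * h[, 7])
      h <- h[h[, 6] / h[, 5] >= min_identity & ev <= max_evalue, ,
             drop = FALSE]
      if (!nrow(h)) next
      for (r in seq_len(nrow(h))) {
        L <- h[r, 5]
        if (L < k) next
        span <- substr(seqs[[qid]], h[r, 1] + 1L, h[r, 2])
        kms <- substring(span, 1:(L - k + 1L), k:L)
        kms <- kms[!grepl("N", kms, fixed = TRUE)]
        if (length(kms)) collected[[length(collected) + 1L]] <- kms
      }
    }
  }
  if (!length(collected)) return(KmerCandidateSet(character(0)))
  tab <- table(unlist(collected, use.names = FALSE))
  kms <- sort(names(tab))
  kms <- kms[homopolymerFilter(kms)]
  KmerCandidateSet(kms, as.integer(tab[kms]))
}

#' POBO-style bootstrap enrichment of one k-mer
#'
#' Draws \code{n_boot} bootstrap replicates of size m = |cluster| with
#' replacement from the cluster promoters and from the background
#' promoters; each replicate yields a mean occurrences-per-promoter.
#' The cluster and background means are the means of the two replicate
#' distributions; fold ratio = cluster mean / background mean; the
#' t statistic and two-sided p-value compare the two replicate
#' distributions (bootstrap-t, anti-conservative by construction).
#'
#' @param kmer ACGT string.
#' @param cluster non-empty \linkS4class{PromoterSet}.
#' @param background \linkS4class{PromoterSet}, at least as large as
#'   the cluster.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param both_strands count the reverse complement too.
#' @return one-row data.frame (an enrichment record): \code{kmer},
#'   \code{cluster_mean}, \code{background_mean}, \code{fold_ratio}
#'   (NA when the background mean is 0), \code{t_statistic},
#'   \code{p_value}, \code{n_boot}, \code{seed}.
#' @export
bootstrapEnrichment <- function(kmer, cluster, background, n_boot = 1000,
                                seed, both_strands = FALSE) {
  if (length(cluster) == 0) stop("cluster must be non-empty")
  if (length(background) < length(cluster))
    stop("background must be at least as large as the cluster")
  cc <- .promoterCounts(kmer, cluster, both_strands)
  bc <- .promoterCounts(kmer, background, both_strands)
  .bootstrapFromCounts(kmer, cc, bc, n_boot, seed)
}

# POBO core on precomputed per-promoter counts.
.bootstrapFromCounts <- function(kmer, cc, bc, n_boot, seed) {
  m <- length(cc)
  withSeed(seed, {
    rep_c <- .colMeans(cc[sample.int(m, m * n_boot, replace = TRUE)],
                       m, n_boot)
    rep_b <- .colMeans(bc[sample.int(length(bc), m * n_boot,
                                     replace = TRUE)], m, n_boot)
    cm <- mean(rep_c); bm <- mean(rep_b)
    if (sd(rep_c) == 0 && sd(rep_b) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(rep_c, rep_b)
    }
    data.frame(kmer = kmer, cluster_mean = cm, background_mean = bm,
               fold_ratio = if (bm > 0) cm / bm else NA_real_,
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               n_boot = as.integer(n_boot), seed = seed,
               stringsAsFactors = FALSE)
  })
}

# Per-promoter counts for many k-mers at once (rows: k-mers).
.promoterCountsMany <- function(kmers, ps, both_strands = FALSE) {
  seqs <- promoterSequences(ps)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  n <- Biostrings::vcountPDict(pd, seqs)
  if (both_strands) {
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    pal <- rcs == kmers
    if (any(!pal)) {
      n2 <- Biostrings::vcountPDict(
        Biostrings::PDict(Biostrings::DNAStringSet(rcs[!pal])), seqs)
      n[!pal, ] <- n[!pal, , drop = FALSE] + n2
    }
  }
  dimnames(n) <- list(kmers, names(seqs))
  n
}

#' Enrichment screen of a gene module
#'
#' Generates shared 6-mer candidates from the module's promoters by
#' all-vs-all alignment, scores each by bootstrap enrichment against
#' the background promoter set, flags the fold-ratio tiers and sorts by
#' decreasing fold ratio.
#'
#' @param module_genes gene ids (>= 2) present in \code{promoters}.
#' @param promoters \linkS4class{PromoterSet} covering the module genes.
#' @param background genome-scale background \linkS4class{PromoterSet}.
#' @param ratio_tiers fold-ratio tier cutoffs (default 2, 3, 4).
#' @param n_boot bootstrap replicates per k-mer (default 1000).
#' @param seed RNG seed.
#' @param both_strands count reverse complements too.
#' @param ... further arguments to \code{\link{sharedKmerCandidates}}.
#' @return data.frame of enrichment records with \code{support} and one
#'   logical \code{tier_<r>} column per tier (tier sets are nested by
#'   construction), sorted by decreasing fold ratio.
#' @export
enrichmentScreen <- function(module_genes, promoters, background,
                             ratio_tiers = c(2, 3, 4), n_boot = 1000,
                             seed, both_strands = FALSE, ...) {
  if (length(module_genes) < 2) stop("module must have at least 2 genes")
  cluster <- promoters[module_genes]
  cand <- sharedKmerCandidates(cluster, ...)
  kms <- candidateKmers(cand)
  empty <- data.frame(kmer = character(0), cluster_mean = numeric(0),
                      background_mean = numeric(0), fold_ratio = numeric(0),
                      t_statistic = numeric(0), p_value = numeric(0),
                      n_boot = integer(0), seed = numeric(0),
                      support = integer(0))
  if (!length(kms)) {
    for (r in ratio_tiers) empty[[paste0("tier_", r)]] <- logical(0)
    return(empty)
  }
  ccm <- .promoterCountsMany(kms, cluster, both_strands)
  bcm <- .promoterCountsMany(kms, background, both_strands)
  recs <- do.call(rbind, lapply(seq_along(kms), function(i)
    .bootstrapFromCounts(kms[i], ccm[i, ], bcm[i, ], n_boot,
                         seed = seed + i - 1L)))
  recs$support <- unname(kmerSupport(cand)[recs$kmer])
  for (r in ratio_tiers)
    recs[[paste0("tier_", r)]] <- !is.na(recs$fold_ratio) & recs$fold_ratio >= r
  recs <- recs[order(-ifelse(is.na(recs$fold_ratio), -Inf, recs$fold_ratio),
                     recs$kmer), ]
  rownames(recs) <- NULL
  recs
}

#' Precision against known elements
#'
#' A found k-mer is a true positive when it is a substring of a known
#' element or a known element is a substring of it, on either strand
#' (the k-mer's reverse complement is also tried).  Precision =
#' nTP / (nTP + nFP); undefined (NA) when nothing was found.
#'
#' @param found a \linkS4class{KmerCandidateSet} or character vector of
#'   k-mers.
#' @param known a \linkS4class{KnownElementList}.
#' @param match_rule only \code{"substring_either_strand"} (default) or
#'   \code{"substring_forward"} are implemented.
#' @return list with \code{nTP}, \code{nFP}, \code{precision}.
#' @export
precisionEval <- function(found, known,
                          match_rule = c("substring_either_strand",
                                         "substring_forward")) {
  match_rule <- match.arg(match_rule)
  if (is(found, "KmerCandidateSet")) found <- candidateKmers(found)
  els <- elements(known)
  isTP <- vapply(found, function(km) {
    forms <- km
    if (match_rule == "substring_either_strand")
      forms <- c(km, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(km))))
    any(vapply(forms, function(f)
      any(grepl(f, els, fixed = TRUE) |
            vapply(els, function(e) grepl(e, f, fixed = TRUE), logical(1))),
      logical(1)))
  }, logical(1))
  nTP <- sum(isTP); nFP <- sum(!isTP)
  list(nTP = nTP, nFP = nFP,
       precision = if (nTP + nFP > 0) nTP / (nTP + nFP) else NA_real_)
}
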