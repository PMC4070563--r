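## Seed-and-extend ungapped local alignment over promoter sets, with
## Karlin-Altschul E-values.  Word seeds are located through an integer
## k-mer index; extension is ungapped in both directions with X-drop
## termination; overlapping hits on the same diagonal are collapsed.

#' Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves sum_ij p_i p_j exp(lambda s(i, j)) = 1 under uniform base
#' composition, i.e. (1/4) e^(lambda * match) + (3/4) e^(lambda *
#' mismatch) = 1, for the unique positive root.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (negative enough to keep the expected
#'   score negative).
#' @return lambda (nats per score unit).
#' @export
karlinAltschulLambda <- function(match = 1, mismatch = -2) {
  if (match <= 0) stop("match score must be positive")
  expected <- 0.25 * match + 0.75 * mismatch
  if (expected >= 0)
    stop("no positive lambda root: expected score must be negative")
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-9, 50 / match), tol = 1e-12)$root
}

#' Karlin-Altschul E-value
#'
#' E = K m n exp(-lambda S): the expected number of chance local
#' alignments scoring >= S between a query of length m and a database
#' of total length n.
#'
#' @param score alignment raw score (> 0).
#' @param m query length.
#' @param n database total length.
#' @param match,mismatch scoring scheme (lambda is solved from them).
#' @param K Karlin-Altschul K constant (default 0.46 for +1/-2).
#' @return E-value (doubling n doubles E; E decreases monotonically in
#'   score).
#' @export
karlinAltschulEvalue <- function(score, m, n, match = 1, mismatch = -2,
                                 K = 0.46) {
  if (any(score <= 0)) stop("score must be positive")
  lambda <- karlinAltschulLambda(match, mismatch)
  K * m * n * exp(-lambda * score)
}

# Integer codes of all k-length windows of a character vector; windows
# containing a non-ACGT character code NA.
.kmerCodes <- function(chars, k) {
  ints <- match(chars, c("A", "C", "G", "T"))
  L <- length(ints)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  code <- rep(0, n)
  for (j in 0:(k - 1L)) {
    code <- code * 4 + (ints[(1L + j):(n + j)] - 1L)
  }
  bad <- rep(FALSE, n)
  nas <- which(is.na(ints))
  for (p in nas) {
    lo <- max(1L, p - k + 1L); hi <- min(n, p)
    bad[lo:hi] <- TRUE
  }
  code[bad] <- NA
  code
}

# Precomputed per-sequence alignment index.
.seqIndex <- function(seq, word_size) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- .kmerCodes(chars, word_size)
  list(chars = chars,
       codes = codes,
       by_code = split(seq_along(codes), codes))
}

# Ungapped X-drop extension along one direction, processed in chunks so
# lookahead never greatly exceeds the realised extension.  qc, sc:
# character vectors; q0, s0: first positions to compare; dirn +1 / -1.
# Returns c(len, score, matches) of the best extension prefix.
.extend <- function(qc, sc, q0, s0, dirn, match, mismatch, x_drop) {
  nmax <- if (dirn > 0) min(length(qc) - q0 + 1L, length(sc) - s0 + 1L)
          else min(q0, s0)
  if (nmax <= 0) return(c(0, 0, 0))
  best_score <- 0; best_len <- 0L; best_matches <- 0L
  run_best <- 0          # max(0, cs[1..t]) so far
  cum_score <- 0; cum_matches <- 0L
  off <- 0L
  while (off < nmax) {
    take <- min(64L, nmax - off)
    idx <- off + seq_len(take)
    a <- qc[q0 + dirn * (idx - 1L)]
    b <- sc[s0 + dirn * (idx - 1L)]
    eq <- a == b & a != "N" & b != "N"
    cs <- cum_score + cumsum(mismatch + (match - mismatch) * eq)
    rm_ <- cummax(pmax(cs, run_best))
    stop_at <- which(cs < rm_ - x_drop)
    lim <- if (length(stop_at)) stop_at[1] else take
    bi <- which.max(cs[seq_len(lim)])
    if (cs[bi] > best_score) {
      best_score <- cs[bi]
      best_len <- off + bi
      best_matches <- cum_matches + sum(eq[seq_len(bi)])
    }
    if (length(stop_at)) break
    cum_score <- cs[take]
    cum_matches <- cum_matches + sum(eq)
    run_best <- rm_[take]
    off <- off + take
  }
  if (best_score <= 0) c(0, 0, 0) else c(best_len, best_score, best_matches)
}

# Align one indexed query against one indexed subject.  Returns a
# numeric matrix with columns q_start, q_end, s_start, s_end (0-based
# half-open), length, matches, score -- or NULL when nothing seeds.
.alignPair <- function(qi, si, word_size, match, mismatch, x_drop) {
  shared <- intersect(names(qi$by_code), names(si$by_code))
  if (!length(shared)) return(NULL)
  qs <- qi$by_code[shared]
  ss <- si$by_code[shared]
  nq <- lengths(qs); ns <- lengths(ss)
  qpos <- unlist(mapply(function(q, r) rep(q, r), qs, ns,
                        SIMPLIFY = FALSE), use.names = FALSE)
  spos <- unlist(mapply(function(s, r) rep(s, each = r), ss, nq,
                        SIMPLIFY = FALSE), use.names = FALSE)
  dg <- qpos - spos
  o <- order(dg, qpos)
  qpos <- qpos[o]; spos <- spos[o]; dg <- dg[o]
  qc <- qi$chars; sc <- si$chars
  acc <- list()
  cur_diag <- NA_integer_; covered_end <- -Inf
  for (r in seq_along(qpos)) {
    qp <- qpos[r]; sp <- spos[r]
    if (is.na(cur_diag) || dg[r] != cur_diag) {
      cur_diag <- dg[r]; covered_end <- -Inf
    }
    if (qp <= covered_end) next
    right <- .extend(qc, sc, qp + word_size, sp + word_size, +1L,
                     match, mismatch, x_drop)
    left <- .extend(qc, sc, qp - 1L, sp - 1L, -1L,
                    match, mismatch, x_drop)
    len <- word_size + right[1] + left[1]
    score <- word_size * match + right[2] + left[2]
    matches <- word_size + right[3] + left[3]
    q_start <- qp - left[1]
    acc[[length(acc) + 1L]] <- c(q_start - 1L, q_start - 1L + len,
                                 sp - left[1] - 1L, sp - left[1] - 1L + len,
                                 len, matches, score)
    covered_end <- q_start - 1L + len
  }
  if (!length(acc)) return(NULL)
  hits <- do.call(rbind, acc)
  # drop hits whose query span lies inside a higher-scoring hit
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits[, 7])
  for (ia in ord) {
    if (!keep[ia]) next
    inside <- hits[, 1] >= hits[ia, 1] & hits[, 2] <= hits[ia, 2] &
      hits[, 7] <= hits[ia, 7] & seq_len(nrow(hits)) != ia
    keep[inside] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

#' Seed-and-extend local alignment of one query against a promoter set
#'
#' Exact word seeds of length \code{word_size} are located via an
#' integer index of the database; each seed is extended without gaps in
#' both directions under +match/-mismatch scoring with X-drop
#' termination.  Hits sharing a diagonal are collapsed (higher score
#' kept); hits whose query span lies inside a higher-scoring hit to the
#' same subject are dropped.  Records with the query's own gene id are
#' skipped (no self-hits).  The E-value search space is query length x
#' database total length.
#'
#' @param query character string (or named length-1 vector; the name is
#'   the query id).
#' @param db a \linkS4class{PromoterSet}.
#' @param word_size seed word length (default 7).
#' @param match,mismatch,x_drop scoring parameters (defaults +1/-2,
#'   X-drop 10).
#' @param K Karlin-Altschul constant for the E-value.
#' @param query_id query gene id (defaults to the name of \code{query}).
#' @return data.frame of hits: \code{query_id}, \code{subject_id},
#'   \code{q_start}, \code{q_end}, \code{s_start}, \code{s_end}
#'   (0-based half-open), \code{length}, \code{identity}, \code{score},
#'   \code{e_value}.
#' @export
seedExtendAlign <- function(query, db, word_size = 7, match = 1,
                            mismatch = -2, x_drop = 10, K = 0.46,
                            query_id = NULL) {
  if (is.null(query_id)) query_id <- names(query)
  if (is.null(query_id)) query_id <- "query"
  query <- toupper(as.character(query))
  if (nchar(query) < word_size) stop("query shorter than word size")
  lambda <- karlinAltschulLambda(match, mismatch)
  qi <- .seqIndex(query, word_size)
  seqs <- as.character(promoterSequences(db))
  out <- list()
  for (sid in names(seqs)) {
    if (identical(sid, query_id)) next
    h <- .alignPair(qi, .seqIndex(seqs[[sid]], word_size),
                    word_size, match, mismatch, x_drop)
    if (is.null(h)) next
    out[[sid]] <- data.frame(query_id = query_id, subject_id = sid,
                             q_start = h[, 1], q_end = h[, 2],
                             s_start = h[, 3], s_end = h[, 4],
                             length = h[, 5],
                             identity = h[, 6] / h[, 5],
                             score = h[, 7],
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      score = numeric(0), e_value = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$e_value <- K * nchar(query) * totalLength(db) * exp(-lambda * res$score)
  res
}
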