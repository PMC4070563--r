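# 24-nt planted element used across the enrichment fixtures; its 19
# constituent 6-mers all pass the homopolymer rule.
elementFixture <- "TGACGTCAGCATGCAATGGCTAAC"
elementKmers <- function(k = 6) {
  L <- nchar(elementFixture)
  sort(unique(substring(elementFixture, 1:(L - k + 1), k:L)))
}

test_that("the homopolymer rule rejects runs of five or more", {
  expect_identical(homopolymerFilter(c("AAAAAG", "AAAAGT", "CCCCCA",
                                       "ACGTAC", "TTTTTT")),
                   c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_error(homopolymerFilter("ACGT"), "length-6")
  expect_error(homopolymerFilter("ACGTAN"), "ACGT")
})

test_that("occurrence counting is overlapping and strand-aware", {
  expect_equal(countOccurrences("ATATAT", "ATATATAT"), 2)   # overlap
  expect_equal(countOccurrences("TGACGT", "TTGACGTT"), 1)
  expect_equal(countOccurrences("TGACGT", "AACGTCAA"), 0)
  # reverse complement of TGACGT is ACGTCA
  expect_equal(countOccurrences("TGACGT", "AACGTCAA", both_strands = TRUE), 1)
  # palindromic k-mers are counted once, not twice
  expect_equal(countOccurrences("GAATTC", "AGAATTCA"), 1)
  expect_equal(countOccurrences("GAATTC", "AGAATTCA", both_strands = TRUE), 1)
  # N never matches
  expect_equal(countOccurrences("TGACGT", "TGACGN"), 0)
})

test_that("alignment-driven candidates are exactly the shared element k-mers", {
  # pads guarantee: no seeds outside the element, immediate mismatch at
  # both element boundaries, so hits are exactly the planted block
  p1 <- paste0(strrep("A", 100), elementFixture, strrep("C", 100))
  p2 <- paste0(strrep("G", 100), elementFixture, strrep("T", 100))
  ps <- PromoterSet(c(g1 = p1, g2 = p2))
  cand <- sharedKmerCandidates(ps)
  expect_identical(candidateKmers(cand), elementKmers())
  # each k-mer is supported by both alignment directions
  expect_true(all(kmerSupport(cand) == 2L))
  expect_error(sharedKmerCandidates(ps["g1"]), "at least 2")
})

test_that("unrelated promoters produce no candidates", {
  set.seed(404)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                         collapse = "")
  ps <- PromoterSet(c(r1 = mk(), r2 = mk(), r3 = mk()))
  expect_equal(length(sharedKmerCandidates(ps)), 0)
})

test_that("bootstrap enrichment reproduces deterministic fold ratios", {
  # constant per-promoter counts: 2 per cluster promoter, 1 per
  # background promoter -> every replicate mean is constant
  clust <- PromoterSet(setNames(
    rep(paste0(strrep("A", 20), "TGACGT", strrep("C", 20),
               "TGACGT", strrep("G", 20)), 4),
    paste0("c", 1:4)))
  bg <- PromoterSet(setNames(
    rep(paste0(strrep("A", 30), "TGACGT", strrep("C", 30)), 6),
    paste0("b", 1:6)))
  rec <- bootstrapEnrichment("TGACGT", clust, bg, n_boot = 50, seed = 9)
  expect_equal(rec$cluster_mean, 2)
  expect_equal(rec$background_mean, 1)
  expect_equal(rec$fold_ratio, 2)
  expect_equal(rec$t_statistic, 0)     # zero-variance replicates
  expect_equal(rec$p_value, 1)
  # absent from the background: fold ratio undefined
  bg0 <- PromoterSet(setNames(rep(strrep("A", 60), 6), paste0("b", 1:6)))
  rec0 <- bootstrapEnrichment("TGACGT", clust, bg0, n_boot = 50, seed = 9)
  expect_true(is.na(rec0$fold_ratio))
  expect_equal(rec0$background_mean, 0)
  expect_error(bootstrapEnrichment("TGACGT", clust, bg["b1"], seed = 1),
               "at least as large")
})

test_that("bootstrap replicates are seed-deterministic and seed-sensitive", {
  tr <- plantedMotifTruth(elementFixture, 2, 0.4)
  out <- synthPromoters(8, 12, length = 400, truth = tr, seed = 71)
  a <- bootstrapEnrichment("TGACGT", out$cluster, out$background,
                           n_boot = 200, seed = 5)
  b <- bootstrapEnrichment("TGACGT", out$cluster, out$background,
                           n_boot = 200, seed = 5)
  c2 <- bootstrapEnrichment("TGACGT", out$cluster, out$background,
                            n_boot = 200, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$t_statistic, c2$t_statistic))
  # the bootstrap means estimate the plain per-promoter means
  plain <- mean(vapply(as.character(promoterSequences(out$cluster)),
                       function(s) countOccurrences("TGACGT", s),
                       integer(1)))
  expect_equal(a$cluster_mean, plain, tolerance = 0.1)
})

test_that("the enrichment screen flags planted elements in the top tier", {
  tr <- plantedMotifTruth(elementFixture, 2, 0.5)
  out <- synthPromoters(20, 40, length = 800, truth = tr, seed = 81)
  scr <- enrichmentScreen(geneIds(out$cluster), out$cluster,
                          out$background, n_boot = 300, seed = 82)
  expect_true(all(c("kmer", "fold_ratio", "p_value", "support",
                    "tier_2", "tier_3", "tier_4") %in% names(scr)))
  # sorted by decreasing fold ratio; tiers are nested
  fr <- scr$fold_ratio[!is.na(scr$fold_ratio)]
  expect_true(all(diff(fr) <= 0))
  expect_true(all(scr$tier_4 <= scr$tier_3))
  expect_true(all(scr$tier_3 <= scr$tier_2))
  # the planted element's own 6-mers are recovered; alignment support
  # (number of supporting hits) singles them out far more sharply than
  # fold ratio, which can crown a rare chance k-mer
  planted_hit <- scr$kmer %in% elementKmers()
  expect_gte(sum(planted_hit), 17)             # >= 17 of the 19 found
  expect_true(planted_hit[which.max(scr$support)])
  expect_gt(median(scr$support[planted_hit]),
            median(scr$support[!planted_hit]))
  expect_gt(sum(planted_hit & scr$tier_3), 0)
  # determinism end to end
  scr2 <- enrichmentScreen(geneIds(out$cluster), out$cluster,
                           out$background, n_boot = 300, seed = 82)
  expect_identical(scr, scr2)
  expect_error(enrichmentScreen("g1", out$cluster, out$background,
                                seed = 1), "at least 2")
})

test_that("precision evaluation honours substrings and strands", {
  known <- KnownElementList(c("TTGACC", "GACG"))
  # TTGACC: equals a known element -> TP on both rules
  # GGTCAA: only its reverse complement (TTGACC) matches -> TP only
  #         when both strands are considered
  # CCCGGG: unrelated (and its own reverse complement) -> FP
  pe <- precisionEval(c("TTGACC", "GGTCAA", "CCCGGG"), known)
  expect_equal(pe$nTP, 2)
  expect_equal(pe$nFP, 1)
  expect_equal(pe$precision, 2 / 3)
  fw <- precisionEval(c("TTGACC", "GGTCAA", "CCCGGG"), known,
                      match_rule = "substring_forward")
  expect_equal(fw$nTP, 1)
  # a known element shorter than the k-mer matches as its substring
  pe2 <- precisionEval("AGACGA", KnownElementList("GACG"))
  expect_equal(pe2$nTP, 1)
  # nothing found: precision undefined
  expect_true(is.na(precisionEval(character(0), known)$precision))
})
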