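# Self-contained ROUGE implementation: ROUGE-N (n-gram co-occurrence) and
# ROUGE-SU4 (skip-bigram with maximum gap 4, plus unigrams). Overlap is
# the clipped multiset intersection, as in the original metric.

#' Count contiguous n-grams with multiplicity
#'
#' @param tokens token vector.
#' @param n n-gram order, `n >= 1`.
#' @return named integer vector: n-gram (tokens joined by a space) ->
#'   count; empty when `length(tokens) < n`.
#' @export
ngramCounts <- function(tokens, n) {
  stopifnot(n >= 1L)
  L <- length(tokens)
  if (L < n) return(setNames(integer(0), character(0)))
  grams <- if (n == 1L) tokens else
    vapply(seq_len(L - n + 1L),
           function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
           character(1))
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

# clipped multiset intersection size
.clippedOverlap <- function(candCounts, refCounts) {
  shared <- intersect(names(candCounts), names(refCounts))
  if (!length(shared)) return(0L)
  sum(pmin(candCounts[shared], refCounts[shared]))
}

.rougeFromCounts <- function(candCounts, refCounts, metric) {
  candTotal <- sum(candCounts)
  refTotal <- sum(refCounts)
  overlap <- .clippedOverlap(candCounts, refCounts)
  recall <- if (refTotal > 0) overlap / refTotal else 0
  precision <- if (candTotal > 0) overlap / candTotal else 0
  f <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  list(metric = metric, recall = recall, precision = precision,
       f_measure = f)
}

#' ROUGE-N co-occurrence scores
#'
#' Recall is the clipped n-gram overlap divided by the reference n-gram
#' count; precision divides by the candidate count; the F measure is their
#' harmonic mean. A reference shorter than `n` has no n-grams, so the
#' scores are 0 with a warning.
#'
#' @param candidateTokens,referenceTokens token vectors.
#' @param n n-gram order.
#' @return list with `metric`, `recall`, `precision`, `f_measure`.
#' @export
rougeN <- function(candidateTokens, referenceTokens, n) {
  stopifnot(n >= 1L)
  refCounts <- ngramCounts(referenceTokens, n)
  if (!sum(refCounts))
    warning("reference has no ", n, "-grams: ROUGE-", n,
            " recall undefined, returning 0", call. = FALSE)
  .rougeFromCounts(ngramCounts(candidateTokens, n), refCounts,
                   paste0("ROUGE-", n))
}

#' Count skip-bigrams with multiplicity
#'
#' All ordered in-sentence pairs `(tokens[i], tokens[j])` with at most
#' `maxGap` intervening words, i.e. `0 < j - i <= maxGap + 1`.
#'
#' @param tokens token vector.
#' @param maxGap maximum number of intervening words (default 4).
#' @return named integer vector: pair (joined by a space) -> count.
#' @export
skipBigrams <- function(tokens, maxGap = 4L) {
  stopifnot(maxGap >= 0L)
  L <- length(tokens)
  if (L < 2L) return(setNames(integer(0), character(0)))
  pairs <- character(0)
  for (i in seq_len(L - 1L)) {
    jmax <- min(L, i + maxGap + 1L)
    pairs <- c(pairs, paste(tokens[i], tokens[(i + 1L):jmax]))
  }
  tab <- table(pairs)
  setNames(as.integer(tab), names(tab))
}

# union multiset of unigrams and gap-4 skip-bigrams; unigram and bigram
# keys cannot collide (bigram keys contain a space)
.su4Counts <- function(tokens) {
  c(ngramCounts(tokens, 1L), skipBigrams(tokens, 4L))
}

#' ROUGE-SU4 scores
#'
#' Skip-bigram (maximum gap four) plus unigram co-occurrence: overlap and
#' totals are computed on the union multiset of both unit types; recall is
#' normalised by the reference's union-multiset size. An empty reference
#' scores 0 with a warning.
#'
#' @param candidateTokens,referenceTokens token vectors.
#' @return list with `metric`, `recall`, `precision`, `f_measure`.
#' @export
rougeSU4 <- function(candidateTokens, referenceTokens) {
  refCounts <- .su4Counts(referenceTokens)
  if (!sum(refCounts))
    warning("empty reference: ROUGE-SU4 undefined, returning 0",
            call. = FALSE)
  .rougeFromCounts(.su4Counts(candidateTokens), refCounts, "ROUGE-SU4")
}

#' Discretized 0-4 relevance grade of a sentence
#'
#' ROUGE-1 recall of the sentence against the reference, binned into five
#' equal-width bins over `[0, 1]` (edges 0.2, 0.4, 0.6, 0.8; recall 1
#' falls in the top bin). Used as the optional coarse labelling mode for
#' training.
#'
#' @param sentenceTokens,referenceTokens token vectors; the reference must
#'   be non-empty.
#' @return integer grade in `0:4`.
#' @export
gradeRouge <- function(sentenceTokens, referenceTokens) {
  if (!length(referenceTokens)) stop("reference must be non-empty")
  r <- rougeN(sentenceTokens, referenceTokens, 1L)$recall
  min(4L, as.integer(floor(r / 0.2)))
}
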