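# Word-set relevance features: GO relevance and LDA topic relevance share
# the same per-occurrence counting scheme — each token occurrence found in
# the word set adds 1, and the total is normalised by sentence length.

.wordSetScore <- function(tokens, wordSet, what) {
  if (!length(tokens)) {
    warning("empty token sequence: ", what, " score undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  sum(tokens %in% wordSet) / length(tokens)
}

#' Gene Ontology relevance of a sentence
#'
#' Fraction of a sentence's token occurrences whose stem appears in the
#' gene's GO word set ([goWordSet()]). Duplicated matching tokens count
#' once per occurrence. Always in `[0, 1]`; `0` for an empty GO word set;
#' an empty sentence scores 0 with a warning (the ratio is otherwise 0/0).
#'
#' @param tokens preprocessed token vector (see [preprocessText()]).
#' @param goWords stemmed GO word set.
#' @return a number in `[0, 1]`.
#' @examples
#' goRelevanceScore(c("actin", "bind", "zinc", "ion"),
#'                  c("bind", "zinc", "ion", "nucleic", "acid"))
#' @export
goRelevanceScore <- function(tokens, goWords) {
  .wordSetScore(tokens, goWords, "GO relevance")
}

#' Topic relevance of a sentence
#'
#' Fraction of a sentence's token occurrences found in the topic word set
#' extracted from the LDA model ([selectTopicWords()]). Same counting and
#' edge conventions as [goRelevanceScore()].
#'
#' @param tokens preprocessed token vector.
#' @param topicWords stemmed topic word set.
#' @return a number in `[0, 1]`.
#' @export
topicRelevanceScore <- function(tokens, topicWords) {
  .wordSetScore(tokens, topicWords, "topic relevance")
}
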