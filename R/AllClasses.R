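#' @import methods
#' @importFrom stats setNames cor runif rnorm
#' @importFrom utils head
#' @useDynLib geneSummarizeR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Corpus-level document statistics
#'
#' Holds the document frequency and inverse document frequency tables used
#' by all tf-idf cosine computations. A "document" is one abstract. The idf
#' of word \eqn{w} is \eqn{1 + \ln(N / n_w)} where \eqn{N} is the number of
#' documents and \eqn{n_w} the number of documents containing \eqn{w}.
#'
#' @slot nDocuments total number of documents \eqn{N}.
#' @slot docFrequency named integer vector, word -> \eqn{n_w}.
#' @slot idf named numeric vector, word -> idf weight.
#' @export
setClass("CorpusStats",
  representation(nDocuments = "integer",
                 docFrequency = "integer",
                 idf = "numeric"))

setValidity("CorpusStats", function(object) {
  msgs <- character(0)
  if (length(object@nDocuments) != 1L || object@nDocuments < 1L)
    msgs <- c(msgs, "nDocuments must be a single positive integer")
  if (length(object@docFrequency) &&
      (any(object@docFrequency < 1L) ||
       any(object@docFrequency > object@nDocuments)))
    msgs <- c(msgs, "document frequencies must lie in [1, nDocuments]")
  if (!identical(names(object@docFrequency), names(object@idf)))
    msgs <- c(msgs, "docFrequency and idf must share names")
  if (length(msgs)) msgs else TRUE
})

#' Per-gene document corpus
#'
#' The central container: candidate sentences (with preprocessed tokens),
#' GO annotations, reference descriptions and the stopword list they were
#' preprocessed with.
#'
#' @slot sentences data.frame with columns sentence_id, gene_id, doc_id,
#'   position (0-based within document), raw_text.
#' @slot tokens list of character vectors, parallel to rows of `sentences`.
#' @slot annotations data.frame with columns tax_id, gene_id, go_id,
#'   go_term, category.
#' @slot references data.frame with columns gene_id, summary_text.
#' @slot referenceTokens list of character vectors, parallel to rows of
#'   `references`.
#' @slot stopwords lowercase stopword list used during preprocessing.
#' @export
setClass("GeneCorpus",
  representation(sentences = "data.frame",
                 tokens = "list",
                 annotations = "data.frame",
                 references = "data.frame",
                 referenceTokens = "list",
                 stopwords = "character"))

setValidity("GeneCorpus", function(object) {
  msgs <- character(0)
  need <- c("sentence_id", "gene_id", "doc_id", "position", "raw_text")
  if (!all(need %in% names(object@sentences)))
    msgs <- c(msgs, paste("sentences must have columns",
                          paste(need, collapse = ", ")))
  if (nrow(object@sentences) != length(object@tokens))
    msgs <- c(msgs, "tokens must be parallel to sentences")
  if (nrow(object@references) != length(object@referenceTokens))
    msgs <- c(msgs, "referenceTokens must be parallel to references")
  if (nrow(object@sentences) &&
      anyDuplicated(paste(object@sentences$gene_id,
                          object@sentences$sentence_id)))
    msgs <- c(msgs, "sentence_id must be unique within gene")
  if (length(msgs)) msgs else TRUE
})

#' Latent Dirichlet Allocation topic model
#'
#' Topic-word distributions estimated by collapsed Gibbs sampling.
#'
#' @slot nTopics number of topics K.
#' @slot topicWordDist K x V matrix; each row a probability distribution
#'   over the vocabulary (columns named by word).
#' @slot vocabulary the model vocabulary (column order of topicWordDist).
#' @slot alpha,beta Dirichlet hyperparameters (document-topic, topic-word).
#' @slot nIterations Gibbs sweeps performed.
#' @slot seed RNG seed the sampler was run with.
#' @export
setClass("TopicModel",
  representation(nTopics = "integer",
                 topicWordDist = "matrix",
                 vocabulary = "character",
                 alpha = "numeric",
                 beta = "numeric",
                 nIterations = "integer",
                 seed = "integer"))

setValidity("TopicModel", function(object) {
  msgs <- character(0)
  if (object@nTopics < 1L) msgs <- c(msgs, "nTopics must be >= 1")
  if (nrow(object@topicWordDist) != object@nTopics)
    msgs <- c(msgs, "topicWordDist must have nTopics rows")
  if (ncol(object@topicWordDist) != length(object@vocabulary))
    msgs <- c(msgs, "topicWordDist columns must match vocabulary")
  if (nrow(object@topicWordDist) &&
      any(abs(rowSums(object@topicWordDist) - 1) > 1e-9))
    msgs <- c(msgs, "each topic's word distribution must sum to 1")
  if (object@alpha <= 0 || object@beta <= 0)
    msgs <- c(msgs, "alpha and beta must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Weighted sentence-similarity graph
#'
#' Undirected graph over one gene's candidate sentences; edge weights are
#' tf-idf cosine similarities. Zero-similarity pairs carry no edge (weight
#' 0 in the matrix).
#'
#' @slot nodes sentence identifiers.
#' @slot weights symmetric numeric matrix of edge weights with zero
#'   diagonal, dimnames = nodes.
#' @export
setClass("SimilarityGraph",
  representation(nodes = "character", weights = "matrix"))

setValidity("SimilarityGraph", function(object) {
  msgs <- character(0)
  w <- object@weights
  n <- length(object@nodes)
  if (!all(dim(w) == c(n, n)))
    msgs <- c(msgs, "weights must be an n x n matrix")
  else {
    if (any(abs(w - t(w)) > 1e-12)) msgs <- c(msgs, "weights must be symmetric")
    if (n && any(diag(w) != 0)) msgs <- c(msgs, "no self-edges allowed")
    if (any(w < 0) || any(w > 1 + 1e-12))
      msgs <- c(msgs, "weights must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Listwise ranking model
#'
#' A linear scoring function f(x) = w . x over the three sentence features
#' (GO relevance, topic relevance, TextRank), trained with the ListNet
#' top-one cross-entropy loss by full-batch gradient descent.
#'
#' @slot weights named numeric triple (go, lda, textrank).
#' @slot lossTrace summed ListNet loss per iteration (length
#'   nIterations + 1; first entry is the loss at the initial weights).
#' @slot learningRate fixed gradient-descent step size.
#' @slot nIterations number of gradient steps taken.
#' @export
setClass("RankingModel",
  representation(weights = "numeric",
                 lossTrace = "numeric",
                 learningRate = "numeric",
                 nIterations = "integer"))

setValidity("RankingModel", function(object) {
  msgs <- character(0)
  if (length(object@weights) != 3L)
    msgs <- c(msgs, "weights must have length 3 (go, lda, textrank)")
  if (!identical(names(object@weights), c("go", "lda", "textrank")))
    msgs <- c(msgs, "weights must be named go, lda, textrank")
  if (length(msgs)) msgs else TRUE
})

#' An extracted gene summary
#'
#' @slot geneId the query gene.
#' @slot sentenceIds selected sentence identifiers, in selection order.
#' @slot sentences raw text of the selected sentences, in selection order.
#' @slot selectionScores the (redundancy-penalised) score each sentence had
#'   at the moment it was selected.
#' @slot originalScores the unpenalised model scores of the same sentences.
#' @slot targetLength requested summary length in sentences.
#' @export
setClass("GeneSummary",
  representation(geneId = "integer",
                 sentenceIds = "character",
                 sentences = "character",
                 selectionScores = "numeric",
                 originalScores = "numeric",
                 targetLength = "integer"))

setValidity("GeneSummary", function(object) {
  msgs <- character(0)
  n <- length(object@sentenceIds)
  if (length(object@sentences) != n ||
      length(object@selectionScores) != n ||
      length(object@originalScores) != n)
    msgs <- c(msgs, "sentence fields must have equal length")
  if (anyDuplicated(object@sentenceIds))
    msgs <- c(msgs, "selected sentences must be unique")
  if (n > object@targetLength)
    msgs <- c(msgs, "summary longer than targetLength")
  if (length(msgs)) msgs else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "CorpusStats", function(object) {
  cat("CorpusStats:", object@nDocuments, "documents,",
      length(object@idf), "words; idf range [",
      if (length(object@idf)) sprintf("%.3f", min(object@idf)) else "-", ",",
      if (length(object@idf)) sprintf("%.3f", max(object@idf)) else "-", "]\n")
})

setMethod("show", "GeneCorpus", function(object) {
  cat("GeneCorpus:", length(unique(object@sentences$gene_id)), "genes,",
      length(unique(paste(object@sentences$gene_id, object@sentences$doc_id))),
      "documents,", nrow(object@sentences), "candidate sentences\n")
  cat("  GO annotations:", nrow(object@annotations),
      " | reference descriptions:", nrow(object@references), "\n")
})

setMethod("show", "TopicModel", function(object) {
  cat("TopicModel: K =", object@nTopics, ", vocabulary =",
      length(object@vocabulary), "words, alpha =", object@alpha,
      ", beta =", object@beta, ",", object@nIterations, "Gibbs sweeps\n")
  if (length(object@vocabulary)) {
    for (k in seq_len(min(object@nTopics, 3L))) {
      top <- names(sort(object@topicWordDist[k, ], decreasing = TRUE))
      cat("  topic", k, ":", paste(head(top, 6L), collapse = " "), "...\n")
    }
  }
})

setMethod("show", "SimilarityGraph", function(object) {
  nEdges <- sum(object@weights[upper.tri(object@weights)] > 0)
  cat("SimilarityGraph:", length(object@nodes), "nodes,", nEdges, "edges\n")
})

setMethod("show", "RankingModel", function(object) {
  cat("RankingModel: f(x) = w . x with w = (",
      paste(sprintf("%s=%.4f", names(object@weights), object@weights),
            collapse = ", "), ")\n")
  if (length(object@lossTrace))
    cat("  trained", object@nIterations, "iterations at step size",
        object@learningRate, "; loss",
        sprintf("%.6f -> %.6f", object@lossTrace[1],
                object@lossTrace[length(object@lossTrace)]), "\n")
})

setMethod("show", "GeneSummary", function(object) {
  cat("GeneSummary for gene", object@geneId, "(",
      length(object@sentences), "of", object@targetLength, "sentences )\n")
  for (i in seq_along(object@sentences))
    cat(sprintf("  [%d] (%.4f) %s\n", i, object@selectionScores[i],
                object@sentences[i]))
})

# ---- accessors --------------------------------------------------------------

#' @rdname CorpusStats-class
#' @param object a `CorpusStats`.
#' @export
nDocuments <- function(object) object@nDocuments

#' Gene identifiers present in a corpus
#' @param corpus a [GeneCorpus-class].
#' @return sorted integer vector of gene ids.
#' @export
geneIds <- function(corpus) sort(unique(corpus@sentences$gene_id))

#' Feature weight vector of a ranking model
#' @param model a [RankingModel-class].
#' @export
modelWeights <- function(model) model@weights

#' Per-iteration training loss of a ranking model
#' @param model a [RankingModel-class].
#' @export
lossTrace <- function(model) model@lossTrace

#' Sentences selected into a summary
#' @param summary a [GeneSummary-class].
#' @return data.frame with sentence_id, raw text, selection and original
#'   scores, in selection order.
#' @export
selectedSentences <- function(summary) {
  data.frame(sentence_id = summary@sentenceIds,
             raw_text = summary@sentences,
             selection_score = summary@selectionScores,
             original_score = summary@originalScores,
             stringsAsFactors = FALSE)
}
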