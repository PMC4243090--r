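# LDA topic modelling of gene description documents. The model is fitted
# by collapsed Gibbs sampling (compiled sampler in src/); the topic most
# related to a gene's documents supplies the topic word set that the
# topic-relevance feature matches sentences against.

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Documents are token vectors; the vocabulary is their union. After
#' `nIterations` full Gibbs sweeps the topic-word distribution is the
#' posterior mean `(n_kw + beta) / (n_k + V beta)` of the final state.
#' Identical inputs and seed give a bit-identical model.
#'
#' @param documents non-empty list of token vectors.
#' @param K number of topics (default 10).
#' @param alpha document-topic Dirichlet parameter (default `50 / K`).
#' @param beta topic-word Dirichlet parameter (default 0.01).
#' @param nIterations Gibbs sweeps (default 1000).
#' @param seed RNG seed.
#' @return a [TopicModel-class].
#' @export
fitLda <- function(documents, K = 10L, alpha = 50 / K, beta = 0.01,
                   nIterations = 1000L, seed = 1L) {
  if (length(documents) < 1L)
    stop("at least one document is required to fit a topic model")
  stopifnot(K >= 1L, alpha > 0, beta > 0, nIterations >= 0L)
  vocab <- sort(unique(unlist(documents)))
  if (!length(vocab)) stop("empty vocabulary: no tokens in any document")
  if (K > length(vocab))
    stop("K (", K, ") exceeds the vocabulary size (", length(vocab), ")")
  word <- match(unlist(documents), vocab) - 1L
  docLen <- lengths(documents)
  doc <- rep(seq_along(documents) - 1L, docLen)
  state <- withSeed(seed, .gibbsLda(as.integer(word), as.integer(doc),
                                    length(vocab), length(documents),
                                    as.integer(K), alpha, beta,
                                    as.integer(nIterations)))
  phi <- (state$nkw + beta) / (state$nk + length(vocab) * beta)
  dimnames(phi) <- list(NULL, vocab)
  new("TopicModel", nTopics = as.integer(K), topicWordDist = phi,
      vocabulary = vocab, alpha = alpha, beta = beta,
      nIterations = as.integer(nIterations), seed = as.integer(seed))
}

# per-document log posterior over topics under a one-topic-per-document
# approximation: log alpha_k + sum_tokens log phi[k, w]; words outside the
# model vocabulary are skipped
.docTopicPosterior <- function(model, tokens) {
  idx <- match(tokens, model@vocabulary)
  idx <- idx[!is.na(idx)]
  logp <- rep(log(model@alpha), model@nTopics)
  if (length(idx)) {
    lphi <- log(model@topicWordDist)
    logp <- logp + vapply(seq_len(model@nTopics),
                          function(k) sum(lphi[k, idx]), numeric(1))
  }
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Select the topic word set for a gene
#'
#' Scores every topic by its summed posterior probability across the
#' gene's documents (each document's topic posterior is computed under a
#' one-topic-per-document approximation) and returns the `topM`
#' highest-probability words of the winning topic.
#'
#' @param model a fitted [TopicModel-class].
#' @param geneDocuments non-empty list of token vectors for the gene.
#' @param topM number of topic words to keep (default 24).
#' @return list with `words` (character set, at most `topM`),
#'   `sourceTopic` (1-based topic index) and `topM`.
#' @export
selectTopicWords <- function(model, geneDocuments, topM = 24L) {
  stopifnot(topM >= 1L)
  if (!length(geneDocuments))
    stop("geneDocuments must contain at least one document")
  post <- vapply(geneDocuments, function(d) .docTopicPosterior(model, d),
                 numeric(model@nTopics))
  total <- if (is.null(dim(post))) post else rowSums(post)
  k <- which.max(total)
  ord <- order(-model@topicWordDist[k, ], model@vocabulary)
  words <- model@vocabulary[ord][seq_len(min(topM, length(model@vocabulary)))]
  list(words = words, sourceTopic = k, topM = as.integer(topM))
}

#' Serialize a topic model to a versioned text file
#'
#' Stores hyperparameters, seed, vocabulary and the full topic-word
#' matrix so summarisation can run without refitting.
#'
#' @param model a [TopicModel-class].
#' @param path output path.
#' @export
writeTopicModel <- function(model, path) {
  header <- sprintf("topicmodel\t1\t%d\t%.17g\t%.17g\t%d\t%d",
                    model@nTopics, model@alpha, model@beta,
                    model@nIterations, model@seed)
  lines <- c(header,
             paste(model@vocabulary, collapse = "\t"),
             vapply(seq_len(model@nTopics), function(k)
               paste(sprintf("%.17g", model@topicWordDist[k, ]),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a topic model written by [writeTopicModel()]
#' @param path model file path.
#' @return a [TopicModel-class].
#' @export
readTopicModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "topicmodel" || header[2] != "1")
    stop("unsupported topic model file version")
  K <- as.integer(header[3])
  vocab <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  phi <- t(vapply(lines[3:(2 + K)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]),
    numeric(length(vocab)), USE.NAMES = FALSE))
  dimnames(phi) <- list(NULL, vocab)
  # renormalise within write/read rounding
  phi <- phi / rowSums(phi)
  new("TopicModel", nTopics = K, topicWordDist = phi, vocabulary = vocab,
      alpha = as.numeric(header[4]), beta = as.numeric(header[5]),
      nIterations = as.integer(header[6]), seed = as.integer(header[7]))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG
#' state, so library internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
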