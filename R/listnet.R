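# Listwise learning to rank (ListNet): a linear scorer f(x) = w . x over
# the three sentence features, trained by full-batch gradient descent on
# the top-one cross-entropy loss between label-induced and score-induced
# permutation probabilities.

#' Construct a query instance
#'
#' One ranking instance: a gene (the query), its candidate sentences'
#' feature vectors and their relevance labels.
#'
#' @param geneId integer gene identifier.
#' @param features numeric matrix, one row per sentence, columns
#'   `go`, `lda`, `textrank`.
#' @param labels numeric relevance labels in `[0, 1]`, one per sentence.
#' @param sentenceIds optional sentence identifiers.
#' @return a list of class `queryInstance`.
#' @export
queryInstance <- function(geneId, features, labels, sentenceIds = NULL) {
  features <- as.matrix(features)
  if (ncol(features) != 3L)
    stop("feature vectors must have arity 3 (go, lda, textrank)")
  if (nrow(features) != length(labels))
    stop("features and labels must have the same length")
  if (nrow(features) < 1L) stop("an instance needs at least one sentence")
  if (is.null(sentenceIds)) sentenceIds <- paste0("s", seq_along(labels))
  colnames(features) <- c("go", "lda", "textrank")
  structure(list(gene_id = as.integer(geneId), features = features,
                 labels = as.numeric(labels),
                 sentence_ids = as.character(sentenceIds)),
            class = "queryInstance")
}

#' Top-one permutation probabilities
#'
#' ListNet's softmax mapping of a score list to the probability that each
#' item ranks first: `P(j) = exp(s_j) / sum_k exp(s_k)`, computed with a
#' max shift for overflow safety.
#'
#' @param scores finite numeric vector, length >= 1.
#' @return probability vector summing to 1.
#' @examples
#' topOneProbabilities(c(0, log(2)))  # 1/3, 2/3
#' @export
topOneProbabilities <- function(scores) {
  stopifnot(length(scores) >= 1L, all(is.finite(scores)))
  e <- exp(scores - max(scores))
  e / sum(e)
}

# log of top-one probabilities, stable
.logTopOne <- function(scores) {
  shifted <- scores - max(scores)
  shifted - log(sum(exp(shifted)))
}

#' ListNet top-one cross-entropy loss
#'
#' `L(y, z) = -sum_j P_y(j) log P_z(j)` where both permutation
#' distributions come from [topOneProbabilities()]. Minimal (equal to the
#' entropy of `P_y`) exactly when the predicted distribution matches the
#' label distribution; zero for single-element lists.
#'
#' @param labels,predicted equal-length numeric vectors.
#' @return the loss, a non-negative number.
#' @export
listnetLoss <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop("labels and predicted scores must have the same length")
  py <- topOneProbabilities(labels)
  -sum(py * .logTopOne(predicted))
}

#' Gradient of the ListNet loss for the linear scorer
#'
#' With `z_j = w . x_j`, the analytic gradient of [listnetLoss()] with
#' respect to `w` is `sum_j (P_z(j) - P_y(j)) x_j`.
#'
#' @param weights numeric triple.
#' @param instance a [queryInstance()].
#' @return numeric triple, the gradient.
#' @export
listnetGradient <- function(weights, instance) {
  z <- as.vector(instance$features %*% weights)
  pz <- topOneProbabilities(z)
  py <- topOneProbabilities(instance$labels)
  as.vector(crossprod(instance$features, pz - py))
}

#' Train the listwise ranking model
#'
#' Full-batch gradient descent with a fixed step size on the sum of the
#' ListNet losses over all query instances (the training objective is
#' `sum_i L(y_i, z_i)`). The objective is convex in the weights, so with
#' the default step size the recorded loss trace is non-increasing.
#' Deterministic: the initial weights come from the caller, not from a
#' random draw.
#'
#' @param instances list of [queryInstance()] objects.
#' @param learningRate fixed step size (default 0.01).
#' @param nIterations gradient steps (default 1000; 0 returns the initial
#'   weights unchanged).
#' @param initWeights starting weight triple (default `(1/3, 1/3, 1/3)`).
#' @return a [RankingModel-class]; its loss trace has `nIterations + 1`
#'   entries beginning with the loss at `initWeights`.
#' @export
trainListnet <- function(instances, learningRate = 0.01,
                         nIterations = 1000L,
                         initWeights = c(1, 1, 1) / 3) {
  stopifnot(length(instances) >= 1L, learningRate > 0,
            nIterations >= 0L, length(initWeights) == 3L)
  w <- as.numeric(initWeights)
  totalLoss <- function(w) {
    tot <- 0
    for (inst in instances)
      tot <- tot + listnetLoss(inst$labels,
                               as.vector(inst$features %*% w))
    tot
  }
  trace <- numeric(nIterations + 1L)
  trace[1L] <- totalLoss(w)
  for (iter in seq_len(nIterations)) {
    g <- c(0, 0, 0)
    for (inst in instances) g <- g + listnetGradient(w, inst)
    w <- w - learningRate * g
    lossNow <- totalLoss(w)
    if (!is.finite(lossNow))
      stop("non-finite training loss at iteration ", iter)
    trace[iter + 1L] <- lossNow
  }
  new("RankingModel", weights = setNames(w, c("go", "lda", "textrank")),
      lossTrace = trace, learningRate = learningRate,
      nIterations = as.integer(nIterations))
}

#' Score feature vectors with a ranking model
#'
#' @param model a [RankingModel-class].
#' @param features numeric matrix with three columns (go, lda, textrank)
#'   or a length-3 vector.
#' @return numeric vector of scores `z_j = w . x_j` in input order.
#' @export
predictScores <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != 3L)
    stop("feature arity mismatch: expected 3 columns, got ", ncol(features))
  as.vector(features %*% model@weights)
}

#' Cosine relevance label of a training sentence
#'
#' The supervision signal: tf-idf cosine similarity between a candidate
#' sentence and the gene's reference description. Lies in `[0, 1]`.
#'
#' @param sentenceTokens preprocessed sentence tokens.
#' @param descriptionTokens preprocessed reference-description tokens;
#'   must be non-empty.
#' @param stats a [CorpusStats-class].
#' @return the label, a number in `[0, 1]`.
#' @export
relevanceLabel <- function(sentenceTokens, descriptionTokens, stats) {
  if (!length(descriptionTokens))
    stop("empty reference description: no relevance label definable")
  tfidfCosine(sentenceTokens, descriptionTokens, stats)
}

#' Write a ranking model as a key-value text file
#' @param model a [RankingModel-class].
#' @param path output path.
#' @export
writeRankingModel <- function(model, path) {
  lines <- c("format_version\t1",
             sprintf("weight_go\t%.17g", model@weights[["go"]]),
             sprintf("weight_lda\t%.17g", model@weights[["lda"]]),
             sprintf("weight_textrank\t%.17g", model@weights[["textrank"]]),
             sprintf("learning_rate\t%.17g", model@learningRate),
             sprintf("n_iterations\t%d", model@nIterations),
             sprintf("initial_loss\t%.17g", model@lossTrace[1]),
             sprintf("final_loss\t%.17g",
                     model@lossTrace[length(model@lossTrace)]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranking model written by [writeRankingModel()]
#' @param path model file path.
#' @return a [RankingModel-class] (loss trace reduced to first/final).
#' @export
readRankingModel <- function(path) {
  kv <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  if (is.na(vals["format_version"]) || vals[["format_version"]] != "1")
    stop("unsupported ranking model file version")
  new("RankingModel",
      weights = setNames(as.numeric(vals[c("weight_go", "weight_lda",
                                           "weight_textrank")]),
                         c("go", "lda", "textrank")),
      lossTrace = as.numeric(vals[c("initial_loss", "final_loss")]),
      learningRate = as.numeric(vals[["learning_rate"]]),
      nIterations = as.integer(vals[["n_iterations"]]))
}
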