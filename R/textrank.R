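# Weighted TextRank over the sentence-similarity graph: nodes are
# sentences, edges are tf-idf cosine similarities, and scores follow the
# damped fixed-point iteration
#   S(V_i) <- (1 - d) + d * sum_{j in In(V_i)} w_ji / deg(V_j) * S(V_j)
# where deg(V_j) is the weighted degree (sum of incident edge weights).

#' tf-idf cosine similarity between two token sequences
#'
#' Each sentence is represented as a vector of `tf(w) * idf(w)` weights
#' over the union vocabulary; the cosine of the two vectors is returned.
#' Words unseen in the corpus statistics receive `idf = 1 + ln(N)` (the
#' smooth extension of the idf formula below one containing document).
#' Either sentence empty gives 0.
#'
#' @param tokensI,tokensJ preprocessed token vectors.
#' @param stats a [CorpusStats-class] object.
#' @return cosine similarity in `[0, 1]`.
#' @export
tfidfCosine <- function(tokensI, tokensJ, stats) {
  if (!length(tokensI) || !length(tokensJ)) return(0)
  vocab <- union(tokensI, tokensJ)
  tfI <- tabulate(match(tokensI, vocab), nbins = length(vocab))
  tfJ <- tabulate(match(tokensJ, vocab), nbins = length(vocab))
  idf <- .idfOf(stats, vocab)
  vI <- tfI * idf
  vJ <- tfJ * idf
  num <- sum(vI * vJ)
  if (num == 0) return(0)
  min(1, num / (sqrt(sum(vI^2)) * sqrt(sum(vJ^2))))
}

#' Build the sentence-similarity graph for one gene
#'
#' One node per sentence; an undirected edge joins every pair with
#' positive tf-idf cosine similarity (zero-similarity pairs carry no
#' edge). Self-similarity is excluded.
#'
#' @param tokens list of preprocessed token vectors, one per sentence.
#' @param stats a [CorpusStats-class].
#' @param nodeIds optional sentence identifiers (defaults to `s1..sn`).
#' @return a [SimilarityGraph-class].
#' @export
buildSimilarityGraph <- function(tokens, stats, nodeIds = NULL) {
  n <- length(tokens)
  if (n < 1L) stop("at least one sentence is required")
  if (is.null(nodeIds)) nodeIds <- paste0("s", seq_len(n))
  stopifnot(length(nodeIds) == n)
  w <- matrix(0, n, n, dimnames = list(nodeIds, nodeIds))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- tfidfCosine(tokens[[i]], tokens[[j]], stats)
        w[i, j] <- w[j, i] <- s
      }
    }
  }
  new("SimilarityGraph", nodes = nodeIds, weights = w)
}

#' Weighted degree of every node
#' @param graph a [SimilarityGraph-class].
#' @return named numeric vector of summed incident edge weights.
#' @export
weightedDegree <- function(graph) rowSums(graph@weights)

#' TextRank scores by damped fixed-point iteration
#'
#' Iterates the weighted PageRank-style update until the largest per-node
#' change falls below `tolerance`. The denominator normalising each
#' neighbour's vote is its weighted degree by default; `denominator =
#' "count"` uses the plain neighbour count instead. Isolated nodes receive
#' exactly `1 - d`; every converged score is at least `1 - d`. The
#' starting value is arbitrary in `[0, 1]` — the fixed point is unique
#' because the iteration is a contraction with factor `d`.
#'
#' @param graph a [SimilarityGraph-class].
#' @param d damping factor in (0, 1); default 0.85.
#' @param tolerance convergence threshold on the max per-node change.
#' @param maxIterations iteration cap; exceeded -> error naming the
#'   residual.
#' @param init initial node value(s) in `[0, 1]` (scalar or per-node).
#' @param denominator `"weight"` (weighted degree, default) or `"count"`
#'   (neighbour count).
#' @return list with `score` (named numeric), `damping`, `tolerance`,
#'   `iterationsUsed`.
#' @export
textrankScores <- function(graph, d = 0.85, tolerance = 1e-6,
                           maxIterations = 1000L, init = 0.5,
                           denominator = c("weight", "count")) {
  stopifnot(d > 0, d < 1, tolerance > 0)
  denominator <- match.arg(denominator)
  w <- graph@weights
  n <- nrow(w)
  deg <- switch(denominator,
                weight = rowSums(w),
                count = rowSums(w > 0))
  # column j of A carries node j's normalised votes; isolated nodes vote 0
  scale <- ifelse(deg > 0, 1 / deg, 0)
  A <- sweep(w, 2L, scale, `*`)
  s <- rep_len(init, n)
  stopifnot(all(s >= 0), all(s <= 1))
  for (iter in seq_len(maxIterations)) {
    sNew <- (1 - d) + d * as.vector(A %*% s)
    delta <- max(abs(sNew - s))
    s <- sNew
    if (delta < tolerance) {
      return(list(score = setNames(s, graph@nodes), damping = d,
                  tolerance = tolerance, iterationsUsed = iter))
    }
  }
  stop("TextRank failed to converge in ", maxIterations,
       " iterations (residual ", format(delta), ")")
}

#' Write a similarity graph as an edge-list TSV
#'
#' Debug helper: tab-separated `node_i node_j weight`, one row per
#' undirected edge with positive weight.
#'
#' @param graph a [SimilarityGraph-class].
#' @param path output path.
#' @export
writeGraphTsv <- function(graph, path) {
  w <- graph@weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  lines <- c("node_i\tnode_j\tweight",
             sprintf("%s\t%s\t%.10g", graph@nodes[idx[, 1]],
                     graph@nodes[idx[, 2]], w[idx]))
  writeLines(lines, path)
  invisible(path)
}
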