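# Shared test helpers: hand-built corpus statistics and tiny corpora.

# CorpusStats with prescribed idf values (for worked examples where the
# idf of each word is stated directly)
statsWithIdf <- function(idf, nDocs = 10L) {
  df <- stats::setNames(rep(1L, length(idf)), names(idf))
  new("CorpusStats", nDocuments = as.integer(nDocs), docFrequency = df,
      idf = stats::setNames(as.numeric(idf), names(idf)))
}

# CorpusStats where every word is equally common (idf = 1), so tf-idf
# cosine reduces to plain tf cosine
uniformStats <- function(words, nDocs = 10L) {
  statsWithIdf(stats::setNames(rep(1, length(words)), words), nDocs)
}

# write a tiny three-gene corpus (plain deterministic text, no RNG) and
# return the three file paths
writeTinyCorpus <- function(dir = tempfile("tiny")) {
  dir.create(dir, showWarnings = FALSE)
  gene2go <- file.path(dir, "gene2go.tsv")
  writeLines(c(
    "tax_id\tGeneID\tGO_ID\tGO_term\tCategory",
    "3702\t814629\tGO:0005575 ND\tcellular_component\tComponent",
    "3702\t814629\tGO:0003676 IEA\tnucleic acid binding\tFunction",
    "3702\t814629\tGO:0008150 ND\tbiological_process\tProcess",
    "3702\t814629\tGO:0008270 IEA\tzinc ion binding\tFunction",
    "3702\t814630\tGO:0016301 IEA\tkinase activity\tFunction"),
    gene2go)
  corpus <- file.path(dir, "corpus.jsonl")
  writeLines(c(
    paste0('{"gene_id": 814629, "doc_id": "d1", "text": "The protein ',
           'binds zinc ions. It also shows nucleic acid binding. ',
           'Unrelated filler sentence about weather patterns."}'),
    paste0('{"gene_id": 814629, "doc_id": "d2", "text": "Zinc ion ',
           'binding was observed in the assay. The assay used purified ',
           'protein."}'),
    paste0('{"gene_id": 814630, "doc_id": "d3", "text": "The kinase ',
           'phosphorylates substrates. Kinase activity increases under ',
           'stress. Lunch was served at noon."}')),
    corpus)
  refs <- file.path(dir, "references.jsonl")
  writeLines(c(
    paste0('{"gene_id": 814629, "summary_text": "This protein binds ',
           'zinc ions and nucleic acids."}'),
    paste0('{"gene_id": 814630, "summary_text": "A kinase that ',
           'phosphorylates substrates under stress."}')),
    refs)
  list(gene2go = gene2go, corpus = corpus, references = refs, dir = dir)
}

# random similarity graph on n nodes with edge density p
randomGraph <- function(n, p = 0.6) {
  w <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) w[i, j] <- w[j, i] <- stats::runif(1)
      }
    }
  }
  ids <- paste0("s", seq_len(n))
  dimnames(w) <- list(ids, ids)
  new("SimilarityGraph", nodes = ids, weights = w)
}

# independent linear-system solution of the TextRank fixed point:
# (I - d * A) s = (1 - d) 1, A column-normalised by weighted degree
textrankLinearSolve <- function(graph, d = 0.85) {
  w <- graph@weights
  n <- nrow(w)
  deg <- colSums(w)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) if (deg[j] > 0) A[, j] <- w[, j] / deg[j]
  as.vector(solve(diag(n) - d * A, rep(1 - d, n)))
}

# brute-force ROUGE-N recall: explicitly enumerate every reference n-gram
# occurrence and greedily match candidate occurrences one by one
bruteRougeRecall <- function(cand, ref, n) {
  grams <- function(x) {
    if (length(x) < n) return(character(0))
    vapply(seq_len(length(x) - n + 1),
           function(i) paste(x[i:(i + n - 1)], collapse = "\r"),
           character(1))
  }
  refG <- grams(ref)
  candG <- grams(cand)
  if (!length(refG)) return(0)
  hits <- 0
  for (g in refG) {
    k <- match(g, candG)
    if (!is.na(k)) {
      hits <- hits + 1
      candG <- candG[-k]
    }
  }
  hits / length(refG)
}
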