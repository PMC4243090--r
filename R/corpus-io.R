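# Reading the corpus formats and the shared text preprocessing (sentence
# splitting, tokenization, stemming, stopword removal).

# abbreviations whose trailing period never ends a sentence
.sentenceAbbrev <- c("al", "e.g", "i.e", "cf", "vs", "fig", "figs",
                     "dr", "st", "no", "ca", "sp", "spp", "approx")

#' Split a document into sentences
#'
#' Deterministic rule-based splitter adequate for abstracts: a sentence
#' ends at a run of `.`, `!` or `?` followed by whitespace and an uppercase
#' letter, or at end of text. A short abbreviation exception list (`et al.`,
#' `e.g.`, `Fig.`, ...) and single-letter initials (`E. coli`) suppress
#' false breaks. Concatenating the result (modulo whitespace) reproduces
#' the input.
#'
#' @param documentText a single character string (may be empty).
#' @return character vector of sentences; `character(0)` for blank input.
#' @examples
#' splitSentences("The gene encodes a protein. It binds zinc.")
#' @export
splitSentences <- function(documentText) {
  stopifnot(is.character(documentText), length(documentText) == 1L)
  if (is.na(documentText) || !nzchar(trimws(documentText)))
    return(character(0))
  m <- gregexpr("[.!?]+", documentText)[[1]]
  breaks <- integer(0)
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      end <- m[k] + lens[k] - 1L
      rest <- substring(documentText, end + 1L)
      if (!grepl("^\\s+[A-Z]", rest)) next
      prev <- substring(documentText, 1L, m[k] - 1L)
      lastWord <- regmatches(prev, regexpr("[A-Za-z.]+$", prev))
      if (length(lastWord) == 1L) {
        if (tolower(lastWord) %in% .sentenceAbbrev) next
        if (grepl("^[A-Z]$", lastWord)) next
      }
      breaks <- c(breaks, end)
    }
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, nchar(documentText))
  out <- trimws(substring(documentText, starts, ends))
  out[nzchar(out)]
}

#' Tokenize, stem and remove stopwords
#'
#' The preprocessing applied to every piece of text in the pipeline:
#' split on non-alphanumeric characters, lowercase, drop tokens shorter
#' than two characters, remove stopwords, then Porter-stem (stopwords are
#' checked again after stemming so no stem equal to a stopword survives).
#'
#' @param rawText character string.
#' @param stopwords lowercase stopword vector; see [defaultStopwords()].
#' @return character vector of stems, in input order (possibly empty).
#' @examples
#' preprocessText("binding proteins", character(0))
#' @export
preprocessText <- function(rawText, stopwords = defaultStopwords()) {
  stopifnot(is.character(rawText), length(rawText) == 1L)
  if (is.na(rawText) || !nzchar(rawText)) return(character(0))
  toks <- strsplit(tolower(rawText), "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) >= 2L]
  toks <- toks[!toks %in% stopwords]
  toks <- porterStem(toks)
  toks[!toks %in% stopwords]
}

#' Packaged English stopword list
#'
#' One lowercase word per line, shipped in `inst/extdata/stopwords.txt`;
#' every preprocessing entry point accepts a user-supplied list instead.
#'
#' @param path optional path to an alternative stopword file.
#' @return character vector of stopwords.
#' @export
defaultStopwords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stopwords.txt",
                        package = "geneSummarizeR", mustWork = TRUE)
  words <- readLines(path, warn = FALSE)
  words <- trimws(words)
  tolower(words[nzchar(words)])
}

.goCategories <- c("Component", "Function", "Process")

#' Read a gene2go annotation table
#'
#' Five tab-separated columns: tax_id, GeneID, GO_ID, GO_term, Category.
#' An evidence code appended to GO_ID after a space (e.g. `GO:0008270 IEA`)
#' is tolerated and stripped. A header line starting with `tax_id` is
#' skipped. Malformed rows raise an error naming the line number.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns tax_id, gene_id, go_id, go_term,
#'   category, rows in file order.
#' @export
readGene2go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(tax_id = integer(0), gene_id = integer(0),
                      go_id = character(0), go_term = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  offset <- 0L
  if (grepl("^#?tax_id\\t", lines[1])) {
    lines <- lines[-1]
    offset <- 1L
  }
  parse1 <- function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 5L)
      stop("gene2go parse error at line ", i + offset, ": expected 5 ",
           "tab-separated fields, found ", length(fields), call. = FALSE)
    taxId <- suppressWarnings(as.integer(fields[1]))
    geneId <- suppressWarnings(as.integer(fields[2]))
    if (is.na(taxId) || is.na(geneId))
      stop("gene2go parse error at line ", i + offset,
           ": non-integer tax_id or GeneID", call. = FALSE)
    goId <- sub("\\s+.*$", "", trimws(fields[3]))
    if (!grepl("^GO:[0-9]{7}$", goId))
      stop("gene2go parse error at line ", i + offset,
           ": malformed GO_ID '", fields[3], "'", call. = FALSE)
    category <- trimws(fields[5])
    if (!category %in% .goCategories)
      stop("gene2go parse error at line ", i + offset,
           ": unknown Category '", category, "'", call. = FALSE)
    list(taxId, geneId, goId, trimws(fields[4]), category)
  }
  rows <- lapply(seq_along(lines), parse1)
  data.frame(tax_id = vapply(rows, function(r) r[[1]], integer(1)),
             gene_id = vapply(rows, function(r) r[[2]], integer(1)),
             go_id = vapply(rows, function(r) r[[3]], character(1)),
             go_term = vapply(rows, function(r) r[[4]], character(1)),
             category = vapply(rows, function(r) r[[5]], character(1)),
             stringsAsFactors = FALSE)
}

#' Write annotations in the gene2go dialect
#'
#' Inverse of [readGene2go()]: writes the five-column TSV with a header
#' line; re-reading yields an identical annotation table.
#'
#' @param annotations data.frame as returned by [readGene2go()].
#' @param path output file path.
#' @export
writeGene2go <- function(annotations, path) {
  lines <- c("tax_id\tGeneID\tGO_ID\tGO_term\tCategory",
             sprintf("%d\t%d\t%s\t%s\t%s",
                     annotations$tax_id, annotations$gene_id,
                     annotations$go_id, annotations$go_term,
                     annotations$category))
  writeLines(lines, path)
  invisible(path)
}

.readJsonl <- function(path, fields) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop("JSONL parse error at line ", i, " of ", path,
                           ": ", conditionMessage(e), call. = FALSE))
    if (!all(fields %in% names(rec)))
      stop("JSONL record at line ", i, " of ", path, " lacks field(s) ",
           paste(setdiff(fields, names(rec)), collapse = ", "),
           call. = FALSE)
    rec
  })
  recs
}

#' Read a JSON-lines abstract corpus
#'
#' One record per line: `{"gene_id": ..., "doc_id": ..., "text": ...}`.
#'
#' @param path path to the corpus file.
#' @return data.frame with columns gene_id (integer), doc_id, text.
#' @export
readCorpusJsonl <- function(path) {
  recs <- .readJsonl(path, c("gene_id", "doc_id", "text"))
  data.frame(
    gene_id = vapply(recs, function(r) as.integer(r$gene_id), integer(1)),
    doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    stringsAsFactors = FALSE)
}

#' Read JSON-lines reference summaries
#'
#' One record per line: `{"gene_id": ..., "summary_text": ...}`.
#'
#' @param path path to the reference file.
#' @return data.frame with columns gene_id (integer), summary_text.
#' @export
readReferencesJsonl <- function(path) {
  recs <- .readJsonl(path, c("gene_id", "summary_text"))
  data.frame(
    gene_id = vapply(recs, function(r) as.integer(r$gene_id), integer(1)),
    summary_text = vapply(recs, function(r) as.character(r$summary_text),
                          character(1)),
    stringsAsFactors = FALSE)
}

.writeJsonl <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' GO word set of a gene
#'
#' Union of the preprocessed (stemmed, stopword-stripped) words of all GO
#' term names annotated to the gene. Duplicate stems collapse; a gene
#' without annotations yields the empty set.
#'
#' @param annotations annotation table from [readGene2go()].
#' @param geneId integer gene identifier.
#' @param stopwords stopword vector.
#' @return character vector (a set) of stems.
#' @export
goWordSet <- function(annotations, geneId, stopwords = defaultStopwords()) {
  terms <- annotations$go_term[annotations$gene_id == geneId]
  if (!length(terms)) return(character(0))
  unique(unlist(lapply(terms, preprocessText, stopwords = stopwords)))
}

#' Compute corpus-level idf statistics
#'
#' One "document" is one abstract. For each word,
#' \eqn{idf(w) = 1 + \ln(N / n_w)}; the natural logarithm is used (any
#' fixed base rescales cosine numerator and denominator jointly, so cosine
#' similarities are base-invariant).
#'
#' @param documents list of token vectors, one per document.
#' @return a [CorpusStats-class] object.
#' @export
computeCorpusStats <- function(documents) {
  if (!length(documents)) stop("at least one document is required")
  n <- length(documents)
  df <- table(unlist(lapply(documents, unique)))
  dfInt <- setNames(as.integer(df), names(df))
  new("CorpusStats", nDocuments = as.integer(n), docFrequency = dfInt,
      idf = 1 + log(n / dfInt))
}

# idf lookup with the smooth unknown-word extension idf = 1 + ln(N)
.idfOf <- function(stats, words) {
  out <- stats@idf[words]
  unknown <- is.na(out)
  if (any(unknown)) out[unknown] <- 1 + log(stats@nDocuments)
  unname(out)
}

#' Assemble a GeneCorpus from its input files
#'
#' Reads the abstract corpus (JSONL), gene2go annotations (TSV) and
#' reference descriptions (JSONL), splits every abstract into sentences
#' and preprocesses all text with the shared tokenizer/stemmer.
#'
#' @param corpusPath JSONL abstract corpus (see [readCorpusJsonl()]).
#' @param gene2goPath gene2go TSV (see [readGene2go()]).
#' @param referencePath JSONL reference summaries; `NULL` if summarising
#'   only (no training labels or evaluation possible then).
#' @param stopwords stopword vector.
#' @return a [GeneCorpus-class].
#' @export
buildGeneCorpus <- function(corpusPath, gene2goPath, referencePath = NULL,
                            stopwords = defaultStopwords()) {
  docs <- readCorpusJsonl(corpusPath)
  annotations <- readGene2go(gene2goPath)
  refs <- if (is.null(referencePath)) {
    data.frame(gene_id = integer(0), summary_text = character(0),
               stringsAsFactors = FALSE)
  } else readReferencesJsonl(referencePath)

  rows <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    sents <- splitSentences(docs$text[i])
    if (!length(sents)) next
    rows[[i]] <- data.frame(
      sentence_id = paste0(docs$doc_id[i], "#", seq_along(sents) - 1L),
      gene_id = docs$gene_id[i],
      doc_id = docs$doc_id[i],
      position = seq_along(sents) - 1L,
      raw_text = sents,
      stringsAsFactors = FALSE)
  }
  sentences <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sentences))
    sentences <- data.frame(sentence_id = character(0), gene_id = integer(0),
                            doc_id = character(0), position = integer(0),
                            raw_text = character(0), stringsAsFactors = FALSE)
  tokens <- lapply(sentences$raw_text, preprocessText, stopwords = stopwords)
  refTokens <- lapply(refs$summary_text, preprocessText,
                      stopwords = stopwords)
  new("GeneCorpus", sentences = sentences, tokens = tokens,
      annotations = annotations, references = refs,
      referenceTokens = refTokens, stopwords = stopwords)
}

#' Corpus statistics of a GeneCorpus
#'
#' Groups the corpus tokens back into abstracts (one document per
#' gene/doc_id pair) and computes [computeCorpusStats()] over them.
#'
#' @param corpus a [GeneCorpus-class].
#' @return a [CorpusStats-class].
#' @export
corpusStats <- function(corpus) {
  key <- paste(corpus@sentences$gene_id, corpus@sentences$doc_id, sep = "\r")
  docs <- lapply(split(corpus@tokens, key), function(x) unlist(x))
  computeCorpusStats(unname(docs))
}

# rows of the sentence table (and their tokens) for one gene, in document
# order as read
.geneSentences <- function(corpus, geneId) {
  idx <- which(corpus@sentences$gene_id == geneId)
  list(table = corpus@sentences[idx, , drop = FALSE],
       tokens = corpus@tokens[idx])
}

.geneReferenceTokens <- function(corpus, geneId) {
  i <- match(geneId, corpus@references$gene_id)
  if (is.na(i)) return(NULL)
  corpus@referenceTokens[[i]]
}
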