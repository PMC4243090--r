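# Porter stemming algorithm (Porter 1980), implemented from the published
# rule tables. Operates on lowercase ASCII words; tokens containing
# non-alphabetic characters (e.g. synthetic vocabulary like "w0042") are
# returned unchanged, as are words shorter than three letters.

.vowels <- c("a", "e", "i", "o", "u")

# consonant test at position i of a letter vector; "y" is a consonant at the
# start of a word or when preceded by a vowel
.isCons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% .vowels) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.isCons(chars, i - 1L))
  }
  TRUE
}

.cvPattern <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  vapply(seq_along(chars), function(i) .isCons(chars, i), logical(1))
}

# m = number of VC sequences in the [C](VC)^m[V] decomposition
.measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .cvPattern(stem)
  m <- 0L
  prev <- TRUE
  for (c_i in cons) {
    if (c_i && !prev) m <- m + 1L   # V -> C transition closes a VC block
    prev <- c_i
  }
  m
}

.containsVowel <- function(stem) {
  nzchar(stem) && any(!.cvPattern(stem))
}

.endsDoubleCons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L)
  b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  cons <- .cvPattern(stem)
  cons[n]
}

# *o: stem ends cvc where the final consonant is not w, x or y
.endsCvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  cons <- .cvPattern(stem)
  last <- substr(stem, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

.endsWith <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n >= k && substr(word, n - k + 1L, n) == suffix
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# rules: list of c(suffix, replacement); applied under the longest-match
# convention — once a suffix matches, no shorter rule is tried even if the
# measure condition fails
.applyRules <- function(word, rules, mmin) {
  ord <- order(-nchar(vapply(rules, `[`, character(1), 1L)))
  for (r in rules[ord]) {
    if (.endsWith(word, r[[1]])) {
      stem <- .chop(word, nchar(r[[1]]))
      if (.measure(stem) > mmin) word <- paste0(stem, r[[2]])
      return(word)
    }
  }
  word
}

.step1a <- function(w) {
  if (.endsWith(w, "sses")) return(paste0(.chop(w, 4L), "ss"))
  if (.endsWith(w, "ies"))  return(paste0(.chop(w, 3L), "i"))
  if (.endsWith(w, "ss"))   return(w)
  if (.endsWith(w, "s"))    return(.chop(w, 1L))
  w
}

.step1b <- function(w) {
  if (.endsWith(w, "eed")) {
    stem <- .chop(w, 3L)
    if (.measure(stem) > 0L) w <- paste0(stem, "ee")
    return(w)
  }
  stripped <- FALSE
  if (.endsWith(w, "ed") && .containsVowel(.chop(w, 2L))) {
    w <- .chop(w, 2L); stripped <- TRUE
  } else if (.endsWith(w, "ing") && .containsVowel(.chop(w, 3L))) {
    w <- .chop(w, 3L); stripped <- TRUE
  }
  if (stripped) {
    if (.endsWith(w, "at") || .endsWith(w, "bl") || .endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.endsDoubleCons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .chop(w, 1L)
    } else if (.measure(w) == 1L && .endsCvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.step1c <- function(w) {
  if (.endsWith(w, "y") && .containsVowel(.chop(w, 1L)))
    w <- paste0(.chop(w, 1L), "i")
  w
}

.step2rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble"))

.step3rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", ""))

.step4suffixes <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                    "ent", "ion", "ism", "ate", "iti", "ous", "ive", "ize",
                    "al", "er", "ic", "ou")

.step4 <- function(w) {
  for (suf in .step4suffixes[order(-nchar(.step4suffixes))]) {
    if (.endsWith(w, suf)) {
      stem <- .chop(w, nchar(suf))
      ok <- .measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

.step5a <- function(w) {
  if (.endsWith(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.endsCvc(stem))) w <- stem
  }
  w
}

.step5b <- function(w) {
  if (.measure(w) > 1L && .endsDoubleCons(w) &&
      .endsWith(w, "l")) w <- .chop(w, 1L)
  w
}

.porterOne <- function(word) {
  if (nchar(word) < 3L || grepl("[^a-z]", word)) return(word)
  w <- .step1a(word)
  w <- .step1b(w)
  w <- .step1c(w)
  w <- .applyRules(w, .step2rules, 0L)
  w <- .applyRules(w, .step3rules, 0L)
  w <- .step4(w)
  w <- .step5a(w)
  .step5b(w)
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter suffix
#' stripping algorithm. Input is lowercased first; words shorter than three
#' letters and tokens containing non-alphabetic characters pass through
#' unchanged (the latter keeps synthetic vocabularies such as `"w0042"`
#' stable under stemming).
#'
#' @param words character vector of words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porterStem(c("binding", "proteins", "relational"))
#' @export
porterStem <- function(words) {
  stopifnot(is.character(words))
  vapply(tolower(words), .porterOne, character(1), USE.NAMES = FALSE)
}
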