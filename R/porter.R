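## Porter stemmer (original 1980 algorithm).
##
## Implemented here because the topic-term display and all token processing
## depend on stems, and stems must be stable across machines. Only purely
## alphabetic tokens are stemmed; tokens containing digits (retained by the
## preprocessing pipeline, e.g. "95") pass through unchanged, as do words of
## one or two letters.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

## classification vector: TRUE = consonant
porter_classify <- function(chars) {
  n <- length(chars)
  out <- logical(n)
  for (i in seq_len(n)) out[i] <- porter_is_cons(chars, i)
  out
}

## m = number of VC sequences in [C](VC)^m[V]
porter_measure <- function(chars) {
  if (length(chars) == 0L) return(0L)
  cons <- porter_classify(chars)
  runs <- rle(cons)$values
  sum(runs[-length(runs)] == FALSE & runs[-1] == TRUE)
}

porter_has_vowel <- function(chars) {
  length(chars) > 0L && any(!porter_classify(chars))
}

porter_ends_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && porter_is_cons(chars, n)
}

## *o: stem ends cvc, where the final c is not w, x or y
porter_ends_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  porter_is_cons(chars, n - 2L) &&
    !porter_is_cons(chars, n - 1L) &&
    porter_is_cons(chars, n) &&
    !(chars[n] %in% c("w", "x", "y"))
}

porter_ends_with <- function(chars, suffix) {
  n <- length(chars)
  k <- nchar(suffix)
  if (n < k) return(FALSE)
  paste0(chars[(n - k + 1L):n], collapse = "") == suffix
}

porter_chop <- function(chars, k) chars[seq_len(length(chars) - k)]

## Apply the longest matching rule of a (suffix -> replacement) table,
## guarded by a condition on the stem. Porter semantics: the longest
## matching suffix selects the rule; if its condition fails, nothing fires.
porter_rule_step <- function(chars, rules, cond) {
  ord <- order(nchar(names(rules)), decreasing = TRUE)
  for (i in ord) {
    suf <- names(rules)[i]
    if (porter_ends_with(chars, suf)) {
      stem <- porter_chop(chars, nchar(suf))
      if (cond(stem)) {
        rep <- rules[[i]]
        if (nzchar(rep)) stem <- c(stem, strsplit(rep, "")[[1]])
        return(stem)
      }
      return(chars)
    }
  }
  chars
}

porter_step1a <- function(chars) {
  if (porter_ends_with(chars, "sses")) return(porter_chop(chars, 2L))
  if (porter_ends_with(chars, "ies")) return(porter_chop(chars, 2L))
  if (porter_ends_with(chars, "ss")) return(chars)
  if (porter_ends_with(chars, "s")) return(porter_chop(chars, 1L))
  chars
}

porter_step1b <- function(chars) {
  if (porter_ends_with(chars, "eed")) {
    stem <- porter_chop(chars, 3L)
    if (porter_measure(stem) > 0L) return(porter_chop(chars, 1L))
    return(chars)
  }
  fired <- FALSE
  if (porter_ends_with(chars, "ed")) {
    stem <- porter_chop(chars, 2L)
    if (porter_has_vowel(stem)) {
      chars <- stem
      fired <- TRUE
    }
  } else if (porter_ends_with(chars, "ing")) {
    stem <- porter_chop(chars, 3L)
    if (porter_has_vowel(stem)) {
      chars <- stem
      fired <- TRUE
    }
  }
  if (fired) {
    if (porter_ends_with(chars, "at") || porter_ends_with(chars, "bl") ||
        porter_ends_with(chars, "iz")) {
      chars <- c(chars, "e")
    } else if (porter_ends_double_cons(chars) &&
               !(chars[length(chars)] %in% c("l", "s", "z"))) {
      chars <- porter_chop(chars, 1L)
    } else if (porter_measure(chars) == 1L && porter_ends_cvc(chars)) {
      chars <- c(chars, "e")
    }
  }
  chars
}

porter_step1c <- function(chars) {
  if (porter_ends_with(chars, "y") &&
      porter_has_vowel(porter_chop(chars, 1L))) {
    chars[length(chars)] <- "i"
  }
  chars
}

.porter_step2_rules <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

.porter_step3_rules <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)

.porter_step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

porter_step4 <- function(chars) {
  ord <- order(nchar(.porter_step4_suffixes), decreasing = TRUE)
  for (i in ord) {
    suf <- .porter_step4_suffixes[i]
    if (porter_ends_with(chars, suf)) {
      stem <- porter_chop(chars, nchar(suf))
      ok <- porter_measure(stem) > 1L
      if (ok && suf == "ion") {
        n <- length(stem)
        ok <- n > 0L && stem[n] %in% c("s", "t")
      }
      if (ok) return(stem)
      return(chars)
    }
  }
  chars
}

porter_step5 <- function(chars) {
  if (porter_ends_with(chars, "e")) {
    stem <- porter_chop(chars, 1L)
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_ends_cvc(stem))) chars <- stem
  }
  if (porter_ends_with(chars, "l") && porter_ends_double_cons(chars) &&
      porter_measure(chars) > 1L) {
    chars <- porter_chop(chars, 1L)
  }
  chars
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)
  chars <- strsplit(word, "")[[1]]
  chars <- porter_step1a(chars)
  chars <- porter_step1b(chars)
  chars <- porter_step1c(chars)
  chars <- porter_rule_step(chars, .porter_step2_rules,
                            function(s) porter_measure(s) > 0L)
  chars <- porter_rule_step(chars, .porter_step3_rules,
                            function(s) porter_measure(s) > 0L)
  chars <- porter_step4(chars)
  chars <- porter_step5(chars)
  paste0(chars, collapse = "")
}

#' Porter stem a vector of tokens
#'
#' Reduces English words to their stems with the classic Porter suffix
#' stripping algorithm (the original 1980 rule set). Tokens that are not
#' purely alphabetic lowercase (for example retained numerals such as
#' `"95"`) and tokens of one or two characters are returned unchanged.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("glycolysis", "fermentation", "confidence", "95"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  if (length(words) == 0L) return(character(0))
  uw <- unique(words)
  stems <- vapply(uw, porter_stem_one, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}
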