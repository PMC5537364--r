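# Porter suffix-stripping stemmer (the 1980 rule set), used for the STEM
# token annotation. Implemented here because stemming is rule-based and
# self-contained; the implementation follows the original rule tables,
# including the "leave words of length <= 2 alone" convention.
#
# Known limitation, relevant to clinical text: like the reference
# algorithm, Greek-derived singular/plural pairs such as
# "metastasis"/"metastases" do NOT conflate (stems "metastasi" vs
# "metastas"); regular English inflections ("node"/"nodes",
# "smokes"/"smoked"/"smoking") do.

.p_is_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1) return(TRUE)
    return(!.p_is_cons(ch, i - 1L)) # y after a consonant acts as a vowel
  }
  TRUE
}

.p_measure <- function(ch) {
  if (length(ch) == 0) return(0L)
  types <- vapply(seq_along(ch), function(i) .p_is_cons(ch, i), logical(1))
  runs <- rle(types)$values
  if (length(runs) > 0 && runs[1]) runs <- runs[-1] # drop leading C run
  sum(runs) # each TRUE left marks the C of a VC pair... count C-runs after a V
}

.p_has_vowel <- function(ch) {
  any(!vapply(seq_along(ch), function(i) .p_is_cons(ch, i), logical(1)))
}

.p_double_cons <- function(ch) {
  n <- length(ch)
  n >= 2 && ch[n] == ch[n - 1] && .p_is_cons(ch, n)
}

.p_cvc <- function(ch) {
  n <- length(ch)
  n >= 3 && .p_is_cons(ch, n) && !.p_is_cons(ch, n - 1L) &&
    .p_is_cons(ch, n - 2L) && !ch[n] %in% c("w", "x", "y")
}

.p_ends <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw >= ns && substr(word, nw - ns + 1L, nw) == suffix
}

.p_chars <- function(word) strsplit(word, "", fixed = TRUE)[[1]]
.p_m <- function(word) .p_measure(.p_chars(word))

# replace suffix if present and condition on the stem holds; returns the
# (possibly unchanged) word plus whether the rule fired
.p_rule <- function(word, suffix, repl, cond = NULL) {
  if (!.p_ends(word, suffix)) return(list(word, FALSE))
  stem <- substr(word, 1L, nchar(word) - nchar(suffix))
  if (!is.null(cond) && !cond(stem)) return(list(word, TRUE)) # matched, blocked
  list(paste0(stem, repl), TRUE)
}

.p_rule_table <- function(word, table, cond) {
  # longest matching suffix wins; condition applies to the residual stem
  sufs <- names(table)
  sufs <- sufs[order(-nchar(sufs))]
  for (s in sufs) {
    if (.p_ends(word, s)) {
      stem <- substr(word, 1L, nchar(word) - nchar(s))
      if (cond(stem)) return(paste0(stem, table[[s]]))
      return(word)
    }
  }
  word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2) return(word)

  # Step 1a
  if (.p_ends(word, "sses")) {
    word <- sub("sses$", "ss", word)
  } else if (.p_ends(word, "ies")) {
    word <- sub("ies$", "i", word)
  } else if (!.p_ends(word, "ss") && .p_ends(word, "s")) {
    word <- sub("s$", "", word)
  }

  # Step 1b
  fired <- FALSE
  if (.p_ends(word, "eed")) {
    stem <- substr(word, 1L, nchar(word) - 3L)
    if (.p_m(stem) > 0) word <- paste0(stem, "ee")
  } else if (.p_ends(word, "ed")) {
    stem <- substr(word, 1L, nchar(word) - 2L)
    if (.p_has_vowel(.p_chars(stem))) { word <- stem; fired <- TRUE }
  } else if (.p_ends(word, "ing")) {
    stem <- substr(word, 1L, nchar(word) - 3L)
    if (.p_has_vowel(.p_chars(stem))) { word <- stem; fired <- TRUE }
  }
  if (fired) {
    if (.p_ends(word, "at") || .p_ends(word, "bl") || .p_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else {
      ch <- .p_chars(word)
      if (.p_double_cons(ch) && !ch[length(ch)] %in% c("l", "s", "z")) {
        word <- substr(word, 1L, nchar(word) - 1L)
      } else if (.p_m(word) == 1 && .p_cvc(.p_chars(word))) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (.p_ends(word, "y")) {
    stem <- substr(word, 1L, nchar(word) - 1L)
    if (.p_has_vowel(.p_chars(stem))) word <- paste0(stem, "i")
  }

  # Step 2
  word <- .p_rule_table(word, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(stem) .p_m(stem) > 0)

  # Step 3
  word <- .p_rule_table(word, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""
  ), function(stem) .p_m(stem) > 0)

  # Step 4
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (s in sufs[order(-nchar(sufs))]) {
    if (.p_ends(word, s)) {
      stem <- substr(word, 1L, nchar(word) - nchar(s))
      ok <- .p_m(stem) > 1
      if (s == "ion") ok <- ok && (.p_ends(stem, "s") || .p_ends(stem, "t"))
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (.p_ends(word, "e")) {
    stem <- substr(word, 1L, nchar(word) - 1L)
    m <- .p_m(stem)
    if (m > 1 || (m == 1 && !.p_cvc(.p_chars(stem)))) word <- stem
  }

  # Step 5b
  ch <- .p_chars(word)
  if (.p_m(word) > 1 && .p_double_cons(ch) && ch[length(ch)] == "l") {
    word <- substr(word, 1L, nchar(word) - 1L)
  }
  word
}

#' Porter stem of words
#'
#' Classic Porter suffix-stripping stemmer. Input is lower-cased before
#' stemming; non-alphabetic strings are returned unchanged.
#'
#' @param words Character vector.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("smoking", "smoked", "smokes"))  # all "smoke"
porter_stem <- function(words) {
  vapply(words, function(w) {
    lw <- tolower(w)
    if (!grepl("^[a-z]+$", lw)) return(lw)
    .porter1(lw)
  }, character(1), USE.NAMES = FALSE)
}
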