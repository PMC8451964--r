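#' Porter stemmer
#'
#' Classic Porter (1980) suffix-stripping algorithm, implemented in pure R.
#' Tokens shorter than three characters, and tokens containing any
#' character outside `a-z` (digits, hyphens — e.g. `"sars-cov-2"`), are
#' returned unchanged; the algorithm is defined on lowercase letter
#' strings only.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("coronavirus", "origin", "relational", "sars-cov-2"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character())
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
  w <- pt_step1a(w)
  w <- pt_step1b(w)
  w <- pt_step1c(w)
  w <- pt_step2(w)
  w <- pt_step3(w)
  w <- pt_step4(w)
  w <- pt_step5a(w)
  pt_step5b(w)
}

# consonant/vowel map: y is a vowel when preceded by a consonant
pt_types <- function(w) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  cons <- logical(length(ch))
  for (i in seq_along(ch)) {
    cons[i] <- if (ch[i] %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (ch[i] == "y") {
      if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      TRUE
    }
  }
  cons
}

# measure m of the [C](VC)^m[V] form
pt_measure <- function(w) {
  if (nchar(w) == 0L) return(0L)
  cons <- pt_types(w)
  sum(diff(cons) == 1L)
}

pt_has_vowel <- function(w) nchar(w) > 0L && any(!pt_types(w))

pt_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  a == b && pt_types(w)[n]
}

# *o condition: ends cvc where the final c is not w, x or y
pt_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cons <- pt_types(w)
  cons[n - 2L] && !cons[n - 1L] && cons[n] &&
    !substr(w, n, n) %in% c("w", "x", "y")
}

pt_ends <- function(w, suf) {
  n <- nchar(w); m <- nchar(suf)
  n > m && substr(w, n - m + 1L, n) == suf
}

pt_chop <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

pt_step1a <- function(w) {
  if (pt_ends(w, "sses")) return(paste0(pt_chop(w, "sses"), "ss"))
  if (pt_ends(w, "ies")) return(paste0(pt_chop(w, "ies"), "i"))
  if (pt_ends(w, "ss")) return(w)
  if (pt_ends(w, "s")) return(pt_chop(w, "s"))
  w
}

pt_step1b <- function(w) {
  if (pt_ends(w, "eed")) {
    stem <- pt_chop(w, "eed")
    if (pt_measure(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  fired <- FALSE
  if (pt_ends(w, "ed") && pt_has_vowel(pt_chop(w, "ed"))) {
    w <- pt_chop(w, "ed"); fired <- TRUE
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_chop(w, "ing"))) {
    w <- pt_chop(w, "ing"); fired <- TRUE
  }
  if (fired) {
    if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (pt_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (pt_measure(w) == 1L && pt_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends(w, "y") && pt_has_vowel(pt_chop(w, "y"))) {
    return(paste0(pt_chop(w, "y"), "i"))
  }
  w
}

pt_rules2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"),
  c("iveness", "ive"), c("fulness", "ful"), c("ousness", "ous"),
  c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

pt_rules3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

pt_apply_rules <- function(w, rules, min_m) {
  for (r in rules) {
    if (pt_ends(w, r[1L])) {
      stem <- pt_chop(w, r[1L])
      if (pt_measure(stem) > min_m) return(paste0(stem, r[2L]))
      return(w)
    }
  }
  w
}

pt_step2 <- function(w) pt_apply_rules(w, pt_rules2, 0L)
pt_step3 <- function(w) pt_apply_rules(w, pt_rules3, 0L)

pt_sufs4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
              "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
              "ous", "ive", "ize")

pt_step4 <- function(w) {
  # longest suffix wins (e.g. "ement" before "ment" before "ent")
  sufs <- pt_sufs4[order(-nchar(pt_sufs4))]
  for (suf in sufs) {
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, suf)
      if (suf == "ion" &&
          !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
        next
      }
      if (pt_measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

pt_step5a <- function(w) {
  if (pt_ends(w, "e")) {
    stem <- pt_chop(w, "e")
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) return(stem)
  }
  w
}

pt_step5b <- function(w) {
  if (pt_measure(w) > 1L && pt_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    return(substr(w, 1L, nchar(w) - 1L))
  }
  w
}
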