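#' The four-word Dutch study lexicon
#'
#' Builds the fixed lexicon used throughout the package: the four Dutch
#' monosyllables *gat* /xαt/, *dat* /dαt/, *gaat* /xat/ and *daad* /dat/,
#' which form a 2x2 design crossing consonant (/x/ vs /d/) and vowel
#' (/α/ vs /a/) identity, plus an "empty" word used for entrainment trains.
#' Each unit carries its log corpus frequency (Corpus Gesproken Nederlands,
#' natural-log scale of occurrence proportion) and a derived high/low
#' frequency class per trait.
#'
#' Node identifiers are ASCII: the open back vowel /α/ is written `"A"`, so
#' `"dAt"` is IPA /dαt/ (orthographic *dat*) and `"dat"` is IPA /dat/
#' (orthographic *daad*). The `"none"` node is the empty word/phoneme.
#'
#' @return An object of class `trait_lexicon`: a list with
#'   \describe{
#'     \item{words}{data.frame of word id, orthography, IPA, log word
#'       frequency and word-frequency class.}
#'     \item{phonemes}{data.frame of phoneme id, trait (consonant/vowel),
#'       log frequency and class.}
#'     \item{word_to_phonemes}{named list mapping each word to its phoneme
#'       ids.}
#'     \item{trait_class}{named list with `consonant`, `vowel`, `word`
#'       character vectors of unit ids classed `"high"`/`"low"`.}
#'     \item{log_frequency}{named numeric over all units.}
#'   }
#' @examples
#' lex <- build_lexicon()
#' lex$trait_class$consonant
#' @export
build_lexicon <- function() {
  words <- data.frame(
    word = c("xAt", "dAt", "xat", "dat", "none"),
    orthography = c("gat", "dat", "gaat", "daad", ""),
    ipa = c("/xɑt/", "/dɑt/", "/xat/", "/dat/", ""),
    log_frequency = c(-10.47, -3.82, -6.41, -11.66, NA),
    stringsAsFactors = FALSE
  )
  phonemes <- data.frame(
    phoneme = c("x", "d", "A", "a", "none"),
    trait = c("consonant", "consonant", "vowel", "vowel", "none"),
    log_frequency = c(-2.53, -1.87, -1.96, -2.29, NA),
    stringsAsFactors = FALSE
  )
  word_to_phonemes <- list(
    xAt = c("x", "A"), dAt = c("d", "A"),
    xat = c("x", "a"), dat = c("d", "a"),
    none = "none"
  )
  class_of <- function(ids, lf) {
    cl <- ifelse(lf >= max(lf), "high", "low")
    # exactly one high / one low within each contrast pair
    stats::setNames(cl, ids)
  }
  trait_class <- list(
    consonant = class_of(c("x", "d"), c(-2.53, -1.87)),
    vowel = class_of(c("A", "a"), c(-1.96, -2.29)),
    word = c(
      xAt = "low", dAt = "high",  # dat (-3.82) and gaat (-6.41) are the
      xat = "high", dat = "low"   # frequent words; gat/daad are rare
    )
  )
  words$word_class <- unname(trait_class$word[words$word])
  phonemes$class <- c(trait_class$consonant[c("x", "d")],
                      trait_class$vowel[c("A", "a")], NA)

  log_frequency <- c(
    stats::setNames(phonemes$log_frequency[1:4], phonemes$phoneme[1:4]),
    stats::setNames(words$log_frequency[1:4], words$word[1:4])
  )

  structure(
    list(words = words, phonemes = phonemes,
         word_to_phonemes = word_to_phonemes,
         trait_class = trait_class, log_frequency = log_frequency),
    class = "trait_lexicon"
  )
}

#' @export
print.trait_lexicon <- function(x, ...) {
  cat("Study lexicon (4 words + empty node)\n")
  print(x$words[, c("word", "orthography", "ipa", "log_frequency",
                    "word_class")], row.names = FALSE)
  invisible(x)
}

#' Input-to-level connectivity matrices
#'
#' The input level consists of the four word nodes plus the empty
#' (entrainment) node. Input-to-phoneme connectivity is 1 when the phoneme
#' belongs to the input word (the empty word connects only to the empty
#' phoneme); input-to-word connectivity is the identity. Under the
#' hierarchical topology the word level is instead driven by the phoneme
#' level through a phoneme-to-word matrix with a 1 wherever the phoneme
#' belongs to the word.
#'
#' @param lexicon a `trait_lexicon` from [build_lexicon()].
#' @param topology `"parallel"` (default; both levels read the input
#'   directly) or `"hierarchical"` (phoneme level feeds the word level).
#' @return An object of class `connectivity`: list with `input_to_phoneme`,
#'   `input_to_word` and (hierarchical only) `phoneme_to_word` matrices, all
#'   with dimnames, plus the topology flag.
#' @export
build_connectivity <- function(lexicon, topology = c("parallel", "hierarchical")) {
  stopifnot(inherits(lexicon, "trait_lexicon"))
  topology <- match.arg(topology)
  input_ids <- lexicon$words$word
  phon_ids <- lexicon$phonemes$phoneme
  word_ids <- lexicon$words$word

  c_ip <- matrix(0, length(input_ids), length(phon_ids),
                 dimnames = list(input_ids, phon_ids))
  for (wd in input_ids)
    c_ip[wd, lexicon$word_to_phonemes[[wd]]] <- 1

  c_iw <- diag(length(input_ids))
  dimnames(c_iw) <- list(input_ids, word_ids)

  out <- list(input_to_phoneme = c_ip, input_to_word = c_iw,
              topology = topology)
  if (topology == "hierarchical") {
    c_pw <- matrix(0, length(phon_ids), length(word_ids),
                   dimnames = list(phon_ids, word_ids))
    for (wd in word_ids)
      c_pw[lexicon$word_to_phonemes[[wd]], wd] <- 1
    out$phoneme_to_word <- c_pw
  }
  structure(out, class = "connectivity")
}
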