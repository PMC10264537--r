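#' Phoneme class labels
#'
#' The eight mutually exclusive classes every ASJP segment is assigned to:
#' the six consonant groups used throughout the analyses (plosive, affricate,
#' approximant, sibilant fricative, non-sibilant fricative, nasal), plus
#' `vowel` and a catch-all `other`.
#'
#' @return Character vector of the eight class labels, consonant groups first.
#' @export
phoneme_classes <- function() {
  c("plosive", "affricate", "approximant", "sibilant_fricative",
    "nonsibilant_fricative", "nasal", "vowel", "other")
}

#' The six consonant groups
#'
#' @return Character vector of the six consonant-group labels.
#' @export
consonant_groups <- function() phoneme_classes()[1:6]

# The 41 single-character ASJP segment symbols (ASJPcode).
ASJP_SYMBOLS <- c(
  "p", "b", "f", "v", "m", "w", "8", "t", "d", "s", "z", "c", "n", "r", "l",
  "S", "Z", "C", "j", "T", "5", "y", "k", "g", "x", "N", "q", "X", "h", "7",
  "L", "4", "G", "!", "i", "e", "E", "3", "a", "u", "o"
)

# Modifier characters: "~" joins the preceding two symbols, "$" the preceding
# three; '"' and "*" mark glottalization/nasalization of the preceding symbol.
ASJP_JOIN2 <- "~"
ASJP_JOIN3 <- "$"
ASJP_ATTACH <- c("\"", "*")
ASJP_MODIFIERS <- c(ASJP_JOIN2, ASJP_JOIN3, ASJP_ATTACH)

#' ASJP vowel symbols
#'
#' The standard ASJP vowel codes: `i`, `e`, `E`, `3`, `a`, `u`, `o`.
#'
#' @return Character vector of the seven vowel symbols.
#' @export
asjp_vowels <- function() c("i", "e", "E", "3", "a", "u", "o")

#' Default ASJP phoneme classification table
#'
#' Maps each ASJP symbol to its phoneme class. The six consonant groups are:
#' plosives `b d g p t k`; affricates `c C j`; approximants `l L w y r`;
#' sibilant fricatives `s z S Z`; non-sibilant fricatives `f v 8 x h X`;
#' nasals `m n N 5`. The seven ASJP vowels map to `vowel`; every remaining
#' ASJP symbol maps to `other`.
#'
#' @return Named character vector: names are ASJP symbols, values are class
#'   labels from [phoneme_classes()].
#' @examples
#' asjp_classification()[["k"]]  # "plosive"
#' asjp_classification()[["w"]]  # "approximant"
#' @export
asjp_classification <- function() {
  tab <- c(
    stats::setNames(rep("plosive", 6), c("b", "d", "g", "p", "t", "k")),
    stats::setNames(rep("affricate", 3), c("c", "C", "j")),
    stats::setNames(rep("approximant", 5), c("l", "L", "w", "y", "r")),
    stats::setNames(rep("sibilant_fricative", 4), c("s", "z", "S", "Z")),
    stats::setNames(rep("nonsibilant_fricative", 6),
                    c("f", "v", "8", "x", "h", "X")),
    stats::setNames(rep("nasal", 4), c("m", "n", "N", "5")),
    stats::setNames(rep("vowel", 7), asjp_vowels())
  )
  rest <- setdiff(ASJP_SYMBOLS, names(tab))
  c(tab, stats::setNames(rep("other", length(rest)), rest))
}

#' Tokenize an ASJP transcription
#'
#' Splits an ASJP-coded string into one token per segment. Whitespace and
#' punctuation separate words in phrases and never yield tokens, so a phrase
#' counts as the concatenation of its words' segments. Symbols are
#' case-sensitive (`s` and `S` are distinct segments).
#'
#' Modifier handling depends on `modifier_mode`:
#' \describe{
#'   \item{`strip`}{(default) modifier characters (`~`, `$`, `"`, `*`) are
#'     deleted and each remaining symbol is its own token.}
#'   \item{`join`}{a trailing `~` merges the preceding two symbols into a
#'     single multi-symbol token, `$` merges three; `"` and `*` attach to the
#'     preceding token.}
#'   \item{`strict`}{any modifier or symbol outside the ASJP inventory is an
#'     error.}
#' }
#'
#' @param asjp Character scalar, an ASCII ASJP transcription (possibly a
#'   multi-word phrase).
#' @param modifier_mode One of `"strip"`, `"join"`, `"strict"`.
#' @return Character vector of tokens; `character(0)` for empty input.
#' @examples
#' tokenize_asjp("spina")            # "s" "p" "i" "n" "a"
#' tokenize_asjp("kp~a", "join")     # "kp~" "a"
#' @export
tokenize_asjp <- function(asjp, modifier_mode = c("strip", "join", "strict")) {
  modifier_mode <- match.arg(modifier_mode)
  stopifnot(is.character(asjp), length(asjp) == 1L, !is.na(asjp))
  if (!all(charToRaw(asjp) <= as.raw(127L))) {
    stop("ASJP transcriptions must be ASCII: ", asjp)
  }
  chars <- strsplit(asjp, "", fixed = TRUE)[[1]]
  # whitespace and non-modifier punctuation separate words, yield no token
  drop <- grepl("[[:space:]]", chars) |
    (grepl("[[:punct:]]", chars) & !chars %in% ASJP_MODIFIERS)
  chars <- chars[!drop]
  if (length(chars) == 0L) return(character(0))

  if (modifier_mode == "strict") {
    bad <- setdiff(unique(chars), ASJP_SYMBOLS)
    if (length(bad) > 0L) {
      stop("unknown or modifier symbol(s) in strict mode: ",
           paste(sQuote(bad), collapse = ", "))
    }
    return(chars)
  }
  if (modifier_mode == "strip") {
    return(chars[!chars %in% ASJP_MODIFIERS])
  }
  # join mode
  tokens <- character(0)
  for (ch in chars) {
    if (ch == ASJP_JOIN2 || ch == ASJP_JOIN3) {
      k <- if (ch == ASJP_JOIN2) 2L else 3L
      n <- length(tokens)
      if (n < k) stop(sQuote(ch), " must follow at least ", k, " symbols")
      joined <- paste0(paste(tokens[(n - k + 1L):n], collapse = ""), ch)
      tokens <- c(tokens[seq_len(n - k)], joined)
    } else if (ch %in% ASJP_ATTACH) {
      n <- length(tokens)
      if (n == 0L) stop(sQuote(ch), " must follow a symbol")
      tokens[n] <- paste0(tokens[n], ch)
    } else {
      tokens <- c(tokens, ch)
    }
  }
  tokens
}

#' Classify phoneme tokens
#'
#' Looks each token up in a classification table. Multi-symbol (joined)
#' tokens are classified by their first symbol. Unknown symbols classify as
#' `other` with a warning; the lookup is total and deterministic.
#'
#' @param tokens Character vector of tokens as returned by [tokenize_asjp()].
#' @param table Named character vector mapping symbols to class labels;
#'   defaults to [asjp_classification()].
#' @return Character vector of class labels, same length as `tokens`.
#' @examples
#' classify_phonemes(c("k", "w", "a"))
#' @export
classify_phonemes <- function(tokens, table = asjp_classification()) {
  if (length(tokens) == 0L) return(character(0))
  stopifnot(all(nzchar(tokens)))
  first <- substr(tokens, 1L, 1L)
  cls <- unname(table[first])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown symbol(s) classified as 'other': ",
            paste(sQuote(unique(first[unknown])), collapse = ", "))
    cls[unknown] <- "other"
  }
  cls
}

#' Count phoneme classes over a set of forms
#'
#' Tokenizes each transcription and tallies tokens by phoneme class. Vowels
#' (and `other` segments) count towards the total number of phonemes, so the
#' class counts always sum to `total_phonemes`.
#'
#' @param asjp Character vector of ASJP transcriptions (one per form), or a
#'   data frame with an `asjp` column (e.g. from [read_wordlist()]).
#' @param table Classification table, see [asjp_classification()].
#' @param modifier_mode Passed to [tokenize_asjp()].
#' @return List with `counts`, a named integer vector over the eight classes
#'   of [phoneme_classes()], and `total_phonemes`, the total token count.
#' @examples
#' group_counts("yog")  # approximant 1, vowel 1, plosive 1; total 3
#' @export
group_counts <- function(asjp, table = asjp_classification(),
                         modifier_mode = "strip") {
  if (is.data.frame(asjp)) asjp <- asjp$asjp
  tokens <- unlist(lapply(asjp, tokenize_asjp, modifier_mode = modifier_mode))
  cls <- factor(classify_phonemes(tokens, table), levels = phoneme_classes())
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, total_phonemes = sum(counts))
}

#' Read a phonemically transcribed wordlist
#'
#' Reads a tab-separated wordlist with columns `language`, `kind`
#' (`target` or `control`), `orthography` and `asjp`. Lines starting with
#' `#` are comments. The target kind holds the swear-word set; the control
#' kind the Swadesh-style list.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return Data frame with the four columns, one row per form.
#' @seealso [write_wordlist()]
#' @export
read_wordlist <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  required <- c("language", "kind", "orthography", "asjp")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("wordlist ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_kind <- !df$kind %in% c("target", "control")
  if (any(bad_kind)) {
    stop("invalid kind at data row(s) ",
         paste(utils::head(which(bad_kind), 5), collapse = ", "),
         ": must be 'target' or 'control'")
  }
  if (any(!nzchar(df$asjp))) {
    stop("empty asjp transcription at data row(s) ",
         paste(utils::head(which(!nzchar(df$asjp)), 5), collapse = ", "))
  }
  df[required]
}

#' Write a wordlist TSV
#'
#' @param forms Data frame with columns `language`, `kind`, `orthography`,
#'   `asjp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wordlist <- function(forms, path) {
  stopifnot(all(c("language", "kind", "orthography", "asjp") %in% names(forms)))
  utils::write.table(forms[c("language", "kind", "orthography", "asjp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
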