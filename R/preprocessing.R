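#' @title Sentence splitting and tokenization for criteria text
#'
#' @description
#' Registry eligibility text is a mix of prose and bullet lists, frequently
#' lacking full stop symbols; a rule-based boundary splitter with an
#' abbreviation rectification pass handles both. Tokenization is lowercase,
#' keeps punctuation as separate tokens (learned patterns retain commas and
#' parentheses as context), and protects slash/ampersand abbreviations such
#' as `m/f` or `msm/w` as single tokens so lexicon features survive.
#'
#' @name preprocessing
NULL

# Abbreviations whose trailing "." must not end a sentence. Matching is
# case-insensitive on the token preceding the stop.
default_abbreviations <- function() {
  c("e.g", "i.e", "etc", "dr", "mr", "mrs", "ms", "vs", "approx", "no",
    "st", "jr", "sr", "fig", "al", "inc", "min", "max")
}

# Tokens kept whole although they contain punctuation (seeded from the
# two-gender / male-abbreviation lexicon features).
default_protected_tokens <- function() {
  c("m/f", "m&f", "msm/w", "msw/m")
}

#' Split a text block into sentences
#'
#' Boundaries are sentence-final punctuation (`.`, `!`, `?`, `;`) followed by
#' whitespace or end of text, newlines, and bullet/numbered list markers
#' (`-`, `*`, `•`, `"1."`, `"1)"`) at line starts. A stop preceded by a
#' known abbreviation or sitting inside a decimal number does not split.
#' Every character of the input belongs to exactly one returned span, so the
#' concatenated spans reproduce the input.
#'
#' @param text A single character string (may be empty).
#' @param trial_id,section Provenance carried on the result.
#' @param abbreviations Abbreviations (without the trailing dot) that never
#'   end a sentence.
#' @return A data frame with columns `trial_id`, `section`, `index`, `text`
#'   (trimmed sentence), `start`, `end` (1-based character span of the
#'   untrimmed sentence in `text`). Empty/whitespace-only input gives zero
#'   rows.
#' @export
#' @examples
#' split_sentences("Inclusion: - Male. - Age 18+.")$text
split_sentences <- function(text, trial_id = NA_character_,
                            section = "OTHER",
                            abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(trial_id = character(0), section = character(0),
                      index = integer(0), text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # candidate boundary AFTER position i
  boundary <- logical(n)

  low <- tolower(text)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("!", "?", ";")) {
      boundary[i] <- TRUE
    } else if (ch == "\n") {
      boundary[i] <- TRUE
    } else if (ch == ".") {
      nxt <- if (i < n) chars[i + 1] else " "
      if (!grepl("[[:space:]]", nxt) && i < n) next  # "3.5", "e.g.," interior
      # decimal numbers: digit.digit never splits (handled above); here the
      # stop is followed by space/end -- veto if preceded by an abbreviation
      prefix <- substr(low, max(1L, i - 12L), i - 1L)
      words <- regmatches(prefix, regexpr("[a-z.]+$", prefix))
      ab <- length(words) == 1 &&
        sub("\\.$", "", words) %in% c(abbreviations, paste0(abbreviations, "."))
      if (!ab) boundary[i] <- TRUE
    }
  }

  # bullet markers open a new sentence: boundary BEFORE the marker
  bullet_at <- integer(0)
  m <- gregexpr("(?m)^[[:blank:]]*(-|\\*|•|[0-9]+[.)])[[:blank:]]+",
                text, perl = TRUE)[[1]]
  if (m[1] != -1) bullet_at <- as.integer(m)
  # also inline bullets after whitespace (" - item")
  m2 <- gregexpr("[[:blank:]](-|•)[[:blank:]]+[A-Za-z0-9]", text,
                 perl = TRUE)[[1]]
  if (m2[1] != -1) bullet_at <- sort(unique(c(bullet_at, as.integer(m2) + 1L)))
  for (p in bullet_at) if (p > 1) boundary[p - 1] <- TRUE

  cuts <- which(boundary)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  texts <- substring(text, starts, ends)
  nonblank <- nzchar(trimws(texts))
  # merge whitespace-only spans into the preceding sentence so the spans
  # still partition the input
  if (any(!nonblank)) {
    out_s <- integer(0); out_e <- integer(0)
    for (j in seq_along(starts)) {
      if (nonblank[j] || length(out_e) == 0) {
        out_s <- c(out_s, starts[j]); out_e <- c(out_e, ends[j])
      } else {
        out_e[length(out_e)] <- ends[j]
      }
    }
    starts <- out_s; ends <- out_e
    texts <- substring(text, starts, ends)
    drop <- !nzchar(trimws(texts))
    starts <- starts[!drop]; ends <- ends[!drop]; texts <- texts[!drop]
  }
  if (length(starts) == 0) return(empty)
  data.frame(trial_id = trial_id, section = section,
             index = seq_along(starts), text = trimws(texts),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

.default_token_regex <- NULL

token_regex <- function(protected = default_protected_tokens()) {
  esc <- gsub("([][{}()+*^$|\\\\?.&/])", "\\\\\\1", protected)
  paste0("(?i)(?:", paste(esc, collapse = "|"),
         ")(?![a-z0-9])|[a-z0-9]+(?:['-][a-z0-9]+)*|[^a-z0-9[:space:]]")
}

# tokens only, skipping offset bookkeeping (hot path)
tokenize_chr <- function(text) {
  if (is.null(.default_token_regex)) {
    utils::assignInMyNamespace(".default_token_regex", token_regex())
  }
  low <- tolower(text)
  m <- regmatches(low, gregexpr(.default_token_regex, low, perl = TRUE))[[1]]
  m
}

#' Tokenize a sentence
#'
#' Lowercased word tokens; punctuation marks are their own tokens; hyphen
#' and apostrophe compounds (`two-gender`) stay whole; protected tokens
#' (`m/f`, `msm/w`, ...) survive as single units.
#'
#' @param text A single string.
#' @param protected Tokens containing punctuation that must not be split.
#' @return A data frame with columns `token` (lowercase surface), `start`,
#'   `end` (1-based character offsets into `text`).
#' @export
#' @examples
#' tokenize("female at birth,")$token
tokenize <- function(text, protected = default_protected_tokens()) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr(token_regex(protected), tolower(text), perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(token = substring(tolower(text), start, end),
             start = start, end = end, stringsAsFactors = FALSE)
}
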