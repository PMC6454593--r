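#' Gender mention lexicon
#'
#' The lexicon maps gender mention types to their surface feature lists.
#' The shipped default covers the mention types `Male`, `Female`,
#' `Two_Gender`, `Biological`, `Transgender`, `Male_Abbreviation`,
#' `Partner` and `Negation_Word`; it lives in
#' `inst/extdata/gender_lexicon.json` and is data, not code: users can point
#' `read_lexicon()` at an edited copy.
#'
#' @param path Path to a JSON file mapping mention type names to character
#'   vectors of lowercase features.
#' @return A named list of character vectors, validated.
#' @export
#' @examples
#' lex <- default_lexicon()
#' names(lex)
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "gender_lexicon.json",
                           package = "trialgender", mustWork = TRUE))
}

#' @rdname default_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lex <- lapply(lex, as.character)
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  stopifnot(is.list(lex), length(names(lex)) == length(lex))
  for (ty in names(lex)) {
    feats <- lex[[ty]]
    if (length(feats) == 0) stop("empty feature list for type ", ty)
    if (any(feats != tolower(feats))) {
      stop("lexicon features must be lowercase (type ", ty, ")")
    }
  }
  if (all(c("Male", "Female") %in% names(lex)) &&
      length(intersect(lex$Male, lex$Female)) > 0) {
    stop("a feature may not belong to both the Male and Female types")
  }
  lex
}

#' Extraction rule configuration
#'
#' Tunable parameters of the composition, verification, sectioning and
#' pattern-slot-typing rules, shipped as an editable JSON file. Fields:
#' `composition$transgender_sex_gap` (max tokens between a Transgender
#' feature and its sex word, default 2), `verification$partner_gap` (max
#' tokens between a mention and a following Partner feature, default 2),
#' `verification$negation_window` (tokens a negation trigger may sit from
#' the mention it governs, default 4), the section header regexes, and
#' `slot_typing` (birth-context cue tokens, max slot length).
#'
#' @param path Path to a rules JSON file.
#' @return A nested list of rule parameters.
#' @export
default_rules <- function() {
  read_rules(system.file("extdata", "extraction_rules.json",
                         package = "trialgender", mustWork = TRUE))
}

#' @rdname default_rules
#' @export
read_rules <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# Precompile a lexicon into an n-gram lookup table: one environment per
# n-gram length, keyed by the space-joined token sequence. Longest features
# are matched first, so multiword features beat their single-word parts.
compile_lexicon <- function(lex, protected = default_protected_tokens()) {
  tabs <- list()
  for (ty in names(lex)) {
    for (feat in lex[[ty]]) {
      toks <- tokenize(feat, protected = protected)$token
      n <- length(toks)
      key <- paste(toks, collapse = " ")
      nm <- as.character(n)
      if (is.null(tabs[[nm]])) tabs[[nm]] <- new.env(parent = emptyenv())
      assign(key, ty, envir = tabs[[nm]])
    }
  }
  lens <- sort(as.integer(names(tabs)), decreasing = TRUE)
  list(tables = tabs, lengths = lens)
}

#' Match lexicon features in a tokenized sentence
#'
#' Longest-match-first, non-overlapping scan over the token sequence: at
#' each position the longest feature starting there wins and consumes its
#' tokens, so `"both genders"` is one `Two_Gender` hit, not a stray
#' `Female` hit on `"genders"`.
#'
#' @param tokens A token data frame from [tokenize()], or a character vector
#'   of tokens.
#' @param lexicon A lexicon list (see [default_lexicon()]) or a compiled
#'   lexicon from the internal compiler.
#' @return A data frame of hits: `type`, `start`, `end` (token indices,
#'   inclusive), `surface`.
#' @export
#' @examples
#' match_lexicon(tokenize("men who have sex with men (msm)"))
match_lexicon <- function(tokens, lexicon = default_lexicon()) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  hits <- match_lexicon_idx(tokens, lexicon)
  data.frame(type = hits$type, start = hits$start, end = hits$end,
             surface = vapply(seq_along(hits$start), function(k) {
               paste(tokens[hits$start[k]:hits$end[k]], collapse = " ")
             }, character(1)),
             stringsAsFactors = FALSE)
}

# internal: same scan returning plain vectors (hot path)
match_lexicon_idx <- function(tokens, lexicon) {
  if (!is.list(lexicon) || is.null(lexicon$tables)) {
    lexicon <- compile_lexicon(lexicon)
  }
  n <- length(tokens)
  out_type <- character(0); out_s <- integer(0); out_e <- integer(0)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L; hit_type <- NA_character_
    for (L in lexicon$lengths) {
      if (i + L - 1L > n) next
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      ty <- get0(key, envir = lexicon$tables[[as.character(L)]],
                 inherits = FALSE)
      if (!is.null(ty)) { hit_len <- L; hit_type <- ty; break }
    }
    if (hit_len > 0L) {
      out_type <- c(out_type, hit_type)
      out_s <- c(out_s, i); out_e <- c(out_e, i + hit_len - 1L)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  list(type = out_type, start = out_s, end = out_e)
}
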