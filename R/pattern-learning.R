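#' @title Windowed transgender pattern learning
#'
#' @description
#' Heuristic rules miss transgender requirements phrased without any
#' transgender keyword, e.g. *"Participants who were female at birth, who
#' now identify as male, will not be excluded"*. Such phrasings are caught
#' by literal token-context patterns learned from an annotated corpus: each
#' annotated span is rewritten to a unified `<TG_Start>...<TG_End>` tag
#' pair, every combination of left/right context windows up to `beta`
#' tokens per side becomes a pattern candidate, candidates are matched back
#' against the corpus, and only candidates with support (count of correct
#' matches) at least `support_threshold` and confidence (correct matches
#' over all matches) at least `confidence_threshold` survive.
#'
#' @name pattern_learning
NULL

#' Pattern learning configuration
#'
#' @param beta Word window length per side of the tag (default 7: the
#'   number of words around the transgender tag is not larger than 7).
#' @param support_threshold Minimum count of correct matches (default 4).
#' @param confidence_threshold Minimum rate of correct matches among all
#'   matches (default 0.7).
#' @param max_slot_tokens Upper bound on slot length during matching
#'   (default 10), guarding against pathological spans.
#' @return A list of class `pattern_config`.
#' @export
pattern_config <- function(beta = 7L, support_threshold = 4L,
                           confidence_threshold = 0.7,
                           max_slot_tokens = 10L) {
  stopifnot(beta >= 1, support_threshold >= 1,
            confidence_threshold > 0, confidence_threshold <= 1,
            max_slot_tokens >= 1)
  structure(list(beta = as.integer(beta),
                 support_threshold = as.integer(support_threshold),
                 confidence_threshold = confidence_threshold,
                 max_slot_tokens = as.integer(max_slot_tokens)),
            class = "pattern_config")
}

# ---- annotated corpus ------------------------------------------------------

#' Normalize an inline-annotated corpus
#'
#' Accepts both supported inline dialects -- `[span text|LABEL]` brackets
#' and the raw `<TG_Start>span text<TG_End>` tag pair (which carries no
#' label and defaults to `TRANSGENDER_ALL`) -- splits each input text into
#' sentences, strips the tags and records each annotated span as token
#' indices. Gold labels are retained for confidence scoring.
#'
#' @param texts Character vector of annotated documents (or sentences).
#' @return A list of annotated sentences, each a list with `text` (clean),
#'   `tokens` (character vector), and `spans` (data frame `start`, `end`
#'   token indices, `label`).
#' @export
#' @examples
#' normalize_annotations(
#'   "Participants who were female at birth, [who now identify as male|TRANSGENDER_MALE], will not be excluded.")
normalize_annotations <- function(texts) {
  out <- list()
  for (d in seq_along(texts)) {
    text <- texts[[d]]
    # unify the tag-pair dialect into the bracket dialect first
    text <- gsub("<TG_Start\\s*>\\s*(.*?)\\s*<\\s*TG_End>",
                 "[\\1|TRANSGENDER_ALL]", text, perl = TRUE)
    if (grepl("<TG_Start|TG_End>", text)) {
      stop("unbalanced TG_Start/TG_End tags in document ", d, call. = FALSE)
    }
    sents <- split_sentences(text)
    for (i in seq_len(nrow(sents))) {
      s <- sents$text[i]
      out[[length(out) + 1L]] <- parse_annotated_sentence(s, where = paste0(
        "document ", d, ", sentence ", i))
    }
  }
  out
}

parse_annotated_sentence <- function(s, where = "") {
  clean <- character(0)
  spans <- data.frame(start = integer(0), end = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  # walk the bracket dialect left to right; nesting is an error
  rest <- s
  clean_txt <- ""
  span_chr <- list()
  while (nzchar(rest)) {
    open <- regexpr("[", rest, fixed = TRUE)
    if (open == -1) { clean_txt <- paste0(clean_txt, rest); break }
    pre <- substr(rest, 1, open - 1)
    rest2 <- substr(rest, open + 1, nchar(rest))
    close <- regexpr("]", rest2, fixed = TRUE)
    pipe <- regexpr("|", rest2, fixed = TRUE)
    if (close == -1 || pipe == -1 || pipe > close) {
      stop("malformed annotation bracket at ", where, call. = FALSE)
    }
    inner <- substr(rest2, 1, close - 1)
    if (grepl("[", inner, fixed = TRUE)) {
      stop("nested annotation at ", where, call. = FALSE)
    }
    span_text <- sub("\\|[^|]*$", "", inner)
    label <- sub("^.*\\|", "", inner)
    clean_txt <- paste0(clean_txt, pre)
    span_chr[[length(span_chr) + 1L]] <-
      c(nchar(clean_txt) + 1L, nchar(clean_txt) + nchar(span_text), label)
    clean_txt <- paste0(clean_txt, span_text)
    rest <- substr(rest2, close + 1, nchar(rest2))
  }
  if (grepl("]", clean_txt, fixed = TRUE) && length(span_chr) > 0) {
    # stray closer outside any bracket is tolerated as plain text
  }
  toks <- tokenize(clean_txt)
  spans <- do.call(rbind, lapply(span_chr, function(sp) {
    cs <- as.integer(sp[1]); ce <- as.integer(sp[2])
    idx <- which(toks$start >= cs & toks$end <= ce)
    if (length(idx) == 0) {
      stop("annotated span holds no tokens at ", where, call. = FALSE)
    }
    data.frame(start = min(idx), end = max(idx), label = sp[3],
               stringsAsFactors = FALSE)
  }))
  if (is.null(spans)) {
    spans <- data.frame(start = integer(0), end = integer(0),
                        label = character(0), stringsAsFactors = FALSE)
  }
  list(text = clean_txt, tokens = toks$token, spans = spans)
}

# ---- candidate extraction --------------------------------------------------

#' Extract pattern candidates from an annotated corpus
#'
#' For every annotated span, all combinations of contiguous left/right
#' context windows with lengths `0..beta` (truncated at sentence edges) are
#' emitted, except the vacuous empty-empty combination. Identical
#' (left, right) context pairs are pooled across spans with multiplicity.
#'
#' @param sentences Annotated sentences from [normalize_annotations()].
#' @param cfg A [pattern_config()].
#' @return A data frame: `left`, `right` (space-joined token contexts, may
#'   be `""`), `occurrences`.
#' @export
extract_candidates <- function(sentences, cfg = pattern_config()) {
  acc <- list()
  for (sent in sentences) {
    toks <- sent$tokens
    sp <- sent$spans
    for (k in seq_len(nrow(sp))) {
      a <- sp$start[k]; b <- sp$end[k]
      lmax <- min(cfg$beta, a - 1L)
      rmax <- min(cfg$beta, length(toks) - b)
      lefts <- c("", vapply(seq_len(lmax), function(l) {
        paste(toks[(a - l):(a - 1L)], collapse = " ")
      }, character(1)))
      rights <- c("", vapply(seq_len(rmax), function(r) {
        paste(toks[(b + 1L):(b + r)], collapse = " ")
      }, character(1)))
      grid <- expand.grid(left = lefts, right = rights,
                          stringsAsFactors = FALSE)[-1, , drop = FALSE]
      acc[[length(acc) + 1L]] <- paste(grid$left, "\r", grid$right)
    }
  }
  keys <- unlist(acc)
  if (length(keys) == 0) {
    return(data.frame(left = character(0), right = character(0),
                      occurrences = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(keys)
  parts <- strsplit(names(tab), " \r ", fixed = TRUE)
  data.frame(
    left = vapply(parts, function(p) p[1], character(1)),
    right = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                   character(1)),
    occurrences = as.integer(tab),
    stringsAsFactors = FALSE, row.names = NULL)
}

# positions where `ctx` (token vector) occurs in `toks`; returns start indices
ctx_positions <- function(toks, ctx) {
  n <- length(toks); m <- length(ctx)
  if (m == 0 || m > n) return(integer(0))
  cand <- which(toks == ctx[1])
  cand <- cand[cand + m - 1L <= n]
  if (m > 1) {
    keep <- vapply(cand, function(i) all(toks[i:(i + m - 1L)] == ctx),
                   logical(1))
    cand <- cand[keep]
  }
  cand
}

# Match one pattern (left/right token vectors) against one token sequence.
# Anchoring: a non-empty left context anchors the slot start; with both
# contexts, a match exists when the right context recurs within
# max_slot tokens (slot is non-greedy). One-sided patterns anchor on their
# single context with a slot capped at max_slot tokens toward the open side.
# Returns a list of parallel integer vectors s (slot starts), e (slot ends).
pattern_matches <- function(toks, left, right, max_slot = 10L) {
  n <- length(toks)
  ls <- length(left); rs <- length(right)
  out_s <- integer(0); out_e <- integer(0)
  if (ls > 0) {
    starts <- ctx_positions(toks, left) + ls  # slot start positions
    if (rs > 0 && length(starts) > 0) rpos_all <- ctx_positions(toks, right)
    for (i in starts) {
      if (i > n) next
      if (rs == 0) {
        out_s <- c(out_s, i)
        out_e <- c(out_e, min(n, i + max_slot - 1L))
      } else {
        rpos <- rpos_all[rpos_all >= i + 1L & rpos_all <= i + max_slot]
        if (length(rpos) > 0) {
          j <- min(rpos) - 1L  # non-greedy slot end
          out_s <- c(out_s, i); out_e <- c(out_e, j)
        }
      }
    }
  } else {
    ends <- ctx_positions(toks, right) - 1L  # slot end positions
    ends <- ends[ends >= 1L]
    out_s <- pmax(1L, ends - max_slot + 1L)
    out_e <- ends
  }
  list(s = out_s, e = out_e)
}

# Pre-split a pattern set's contexts for repeated matching; the anchor
# token allows a cheap reject of sentences that cannot match.
compile_patterns <- function(patterns) {
  if (inherits(patterns, "compiled_patterns")) return(patterns)
  compiled <- lapply(seq_len(nrow(patterns)), function(i) {
    L <- strsplit(patterns$left[i], " ", fixed = TRUE)[[1]]
    R <- strsplit(patterns$right[i], " ", fixed = TRUE)[[1]]
    L <- L[nzchar(L)]; R <- R[nzchar(R)]
    # anchor on the rarest-looking context token: prefer a word over
    # punctuation so the reject actually bites
    ctx <- c(L, R)
    words <- ctx[grepl("[a-z0-9]", ctx)]
    anchor <- if (length(words) > 0) words[which.max(nchar(words))] else ctx[1]
    list(left = L, right = R, anchor = anchor,
         context_len = length(L) + length(R))
  })
  structure(list(patterns = compiled, set = patterns),
            class = "compiled_patterns")
}

# A match is correct when a gold span is consistent with its anchors: for a
# non-empty left context the span must start at the slot start and (if a
# right context exists) be followed by it; an empty-left pattern requires a
# gold span ending at the slot end.
match_is_correct <- function(toks, spans, left, right, slot_start, slot_end,
                             max_slot = 10L) {
  ls <- length(left); rs <- length(right)
  for (k in seq_len(nrow(spans))) {
    a <- spans$start[k]; b <- spans$end[k]
    if (b - a + 1L > max_slot) next
    if (ls > 0) {
      if (a != slot_start) next
      if (rs > 0) {
        after <- b + 1L
        if (after + rs - 1L > length(toks)) next
        if (!all(toks[after:(after + rs - 1L)] == right)) next
      }
      return(TRUE)
    } else {
      if (b == slot_end) return(TRUE)
    }
  }
  FALSE
}

#' Score pattern candidates by support and confidence
#'
#' Every candidate is matched back against every annotated sentence. A
#' match is correct when its slot aligns with a gold-annotated span;
#' support is the count of correct matches and confidence the rate of
#' correct matches among all matches. Candidates that never match are
#' dropped (their confidence is undefined).
#'
#' @param candidates Candidate data frame from [extract_candidates()].
#' @param corpus Annotated sentences from [normalize_annotations()].
#' @param cfg A [pattern_config()].
#' @return The candidate frame with `support` and `confidence` columns.
#' @export
score_patterns <- function(candidates, corpus, cfg = pattern_config()) {
  nc <- nrow(candidates)
  support <- integer(nc); total <- integer(nc)
  lefts <- strsplit(candidates$left, " ", fixed = TRUE)
  rights <- strsplit(candidates$right, " ", fixed = TRUE)
  lefts <- lapply(lefts, function(x) x[nzchar(x)])
  rights <- lapply(rights, function(x) x[nzchar(x)])
  # inverted index on anchor token to skip hopeless sentences
  anchor <- vapply(seq_len(nc), function(i) {
    if (length(lefts[[i]]) > 0) lefts[[i]][1] else rights[[i]][1]
  }, character(1))
  sent_tokens <- lapply(corpus, function(s) s$tokens)
  has_token <- lapply(sent_tokens, unique)
  for (i in seq_len(nc)) {
    L <- lefts[[i]]; R <- rights[[i]]
    for (si in seq_along(corpus)) {
      if (!(anchor[i] %in% has_token[[si]])) next
      toks <- sent_tokens[[si]]
      mm <- pattern_matches(toks, L, R, cfg$max_slot_tokens)
      if (length(mm$s) == 0) next
      total[i] <- total[i] + length(mm$s)
      sp <- corpus[[si]]$spans
      if (nrow(sp) == 0) next
      for (r in seq_along(mm$s)) {
        if (match_is_correct(toks, sp, L, R, mm$s[r], mm$e[r],
                             cfg$max_slot_tokens)) {
          support[i] <- support[i] + 1L
        }
      }
    }
  }
  res <- candidates
  res$support <- support
  res$confidence <- ifelse(total > 0, support / total, NA_real_)
  res[total > 0, , drop = FALSE]
}

#' Filter scored candidates into a pattern set
#'
#' Keeps candidates with `support >= support_threshold` and
#' `confidence >= confidence_threshold` (values strictly lower than the
#' thresholds are invalid), deduplicated and sorted by support descending,
#' confidence descending, then lexicographically.
#'
#' @param scored Scored candidates from [score_patterns()].
#' @param cfg A [pattern_config()].
#' @return A data frame of class `pattern_set`.
#' @export
filter_patterns <- function(scored, cfg = pattern_config()) {
  keep <- !is.na(scored$confidence) &
    scored$support >= cfg$support_threshold &
    scored$confidence >= cfg$confidence_threshold
  out <- scored[keep, c("left", "right", "support", "confidence"),
                drop = FALSE]
  out <- unique(out)
  if (nrow(out) > 0) {
    key <- paste(out$left, "<TG>", out$right)
    out <- out[order(-out$support, -out$confidence, key), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("pattern_set", "data.frame")
  out
}

#' Learn transgender matching patterns from an annotated corpus
#'
#' Convenience wrapper: normalize, extract candidates, score, filter.
#'
#' @param texts Annotated documents (see [normalize_annotations()]).
#' @param cfg A [pattern_config()].
#' @return A `pattern_set` data frame.
#' @export
#' @examples
#' corp <- rep("were female at birth, [who identify as male|TRANSGENDER_MALE], will not", 5)
#' learn_patterns(corp)[1:2, ]
learn_patterns <- function(texts, cfg = pattern_config()) {
  corpus <- normalize_annotations(texts)
  cand <- extract_candidates(corpus, cfg)
  scored <- score_patterns(cand, corpus, cfg)
  filter_patterns(scored, cfg)
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> ", nrow(x), " patterns\n", sep = "")
  if (nrow(x) > 0) {
    shown <- utils::head(x, 10)
    cat(sprintf(" [s=%d c=%.2f] %s <TG> %s\n", shown$support,
                shown$confidence, shown$left, shown$right), sep = "")
    if (nrow(x) > 10) cat(" ...\n")
  }
  invisible(x)
}

#' Read and write pattern sets as JSON lines
#'
#' One JSON object per line: `{"left": [...], "right": [...],
#' "support": n, "confidence": x}`.
#'
#' @param patterns A `pattern_set`.
#' @param path File path.
#' @return `read_patterns()` returns a `pattern_set`.
#' @export
write_patterns <- function(patterns, path) {
  lines <- vapply(seq_len(nrow(patterns)), function(i) {
    jsonlite::toJSON(list(
      left = strsplit(patterns$left[i], " ", fixed = TRUE)[[1]],
      right = strsplit(patterns$right[i], " ", fixed = TRUE)[[1]],
      support = patterns$support[i],
      confidence = patterns$confidence[i]
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    data.frame(left = paste(x$left, collapse = " "),
               right = paste(x$right, collapse = " "),
               support = as.integer(x$support),
               confidence = as.numeric(x$confidence),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(left = character(0), right = character(0),
                      support = integer(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("pattern_set", "data.frame")
  out
}

#' Match a pattern set against a tokenized sentence
#'
#' Returns the transgender mention candidate slots: token spans whose
#' surrounding contexts match a pattern. Overlapping hits from several
#' patterns are merged into one span; the hit from the pattern with the
#' most context tokens wins the span boundaries and all contributing
#' patterns are recorded.
#'
#' @param tokens Token character vector (or [tokenize()] frame).
#' @param patterns A `pattern_set`.
#' @param max_slot Maximum slot length in tokens.
#' @return Data frame: `slot_start`, `slot_end`, `pattern` (index of the
#'   winning pattern), `patterns` (list column of all contributing pattern
#'   indices).
#' @export
match_patterns <- function(tokens, patterns, max_slot = 10L) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  cp <- compile_patterns(patterns)
  hs <- integer(0); he <- integer(0); hp <- integer(0); hc <- integer(0)
  for (i in seq_along(cp$patterns)) {
    p <- cp$patterns[[i]]
    if (!(p$anchor %in% tokens)) next
    mm <- pattern_matches(tokens, p$left, p$right, max_slot)
    if (length(mm$s) > 0) {
      hs <- c(hs, mm$s); he <- c(he, mm$e)
      hp <- c(hp, rep(i, length(mm$s)))
      hc <- c(hc, rep(p$context_len, length(mm$s)))
    }
  }
  if (length(hs) == 0) {
    return(data.frame(slot_start = integer(0), slot_end = integer(0),
                      pattern = integer(0)))
  }
  # merge overlapping slots: widest-context pattern owns the span
  ord <- order(-hc, hs)
  hs <- hs[ord]; he <- he[ord]; hp <- hp[ord]
  merged <- list()
  for (r in seq_along(hs)) {
    placed <- FALSE
    for (m in seq_along(merged)) {
      if (hs[r] <= merged[[m]]$slot_end && he[r] >= merged[[m]]$slot_start) {
        merged[[m]]$patterns <- union(merged[[m]]$patterns, hp[r])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      merged[[length(merged) + 1L]] <- list(
        slot_start = hs[r], slot_end = he[r],
        pattern = hp[r], patterns = hp[r])
    }
  }
  out <- data.frame(
    slot_start = vapply(merged, function(m) m$slot_start, integer(1)),
    slot_end = vapply(merged, function(m) m$slot_end, integer(1)),
    pattern = vapply(merged, function(m) m$pattern, integer(1)))
  out$patterns <- lapply(merged, function(m) sort(m$patterns))
  out[order(out$slot_start), , drop = FALSE]
}
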