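#' @title Gender mention extraction (rules + patterns + verification)
#'
#' @description
#' The feature extraction stage detects gender mentions sentence by
#' sentence. Learned patterns fire first; heuristic composition rules then
#' turn lexicon hits into typed mentions (`Transgender` + sex word ->
#' transgender mention, bare sex word -> biological mention, ...).
#' Context verification demotes partner-governed mentions to irrelevant and
#' flips negated mentions, and section logic inverts polarity inside
#' exclusion criteria.
#'
#' @name extraction
NULL

.empty_mentions <- NULL

mention_frame <- function() {
  if (is.null(.empty_mentions)) {
    utils::assignInMyNamespace(".empty_mentions", data.frame(
      trial_id = character(0), section = character(0),
      sentence_index = integer(0), start = integer(0),
      end = integer(0), surface = character(0),
      composite = character(0), polarity = character(0),
      provenance = character(0), trigger_start = integer(0),
      trigger_end = integer(0), stringsAsFactors = FALSE))
  }
  .empty_mentions
}

# vectorized mention constructor (one data.frame for all rows)
new_mention <- function(start, end, surface, composite,
                        polarity = "ASSERTED", provenance = "RULE") {
  n <- length(start)
  data.frame(trial_id = rep(NA_character_, n), section = NA_character_,
             sentence_index = NA_integer_, start = start, end = end,
             surface = surface, composite = composite, polarity = polarity,
             provenance = provenance, trigger_start = NA_integer_,
             trigger_end = NA_integer_, stringsAsFactors = FALSE)
}

#' Compose typed gender mentions from lexicon hits
#'
#' Adjacency composition over typed hits, most specific first and each hit
#' consumed at most once:
#' a `Transgender` hit pairs with a `Male`/`Female` hit within a small
#' token gap (either order) into a transgender mention; a `Biological` hit
#' pairs with a sex hit into a biological mention; a lone `Transgender`
#' hit is `TRANSGENDER_ALL` (an unsexed transgender mention covers both
#' identities); a lone `Biological` hit is `BIOLOGICAL_ALL`; bare
#' `Male`/`Female`/`Male_Abbreviation` hits are biological sexes; a
#' `Two_Gender` hit is `BIOLOGICAL_ALL`. `Partner` and `Negation_Word`
#' hits are context features, not mentions.
#'
#' @param hits Hit frame from [match_lexicon()].
#' @param tokens Token character vector of the sentence.
#' @param rules Rule configuration ([default_rules()]).
#' @return A mention data frame (token-span rows with `composite` and
#'   `polarity = "ASSERTED"`).
#' @export
#' @examples
#' toks <- tokenize("self identify as a transgender woman")
#' compose_mentions(match_lexicon(toks), toks$token)
compose_mentions <- function(hits, tokens, rules = default_rules()) {
  n_hits <- length(hits$type)
  if (n_hits == 0) return(mention_frame())
  ms <- integer(0); me <- integer(0); mcomp <- character(0)
  used <- rep(FALSE, n_hits)
  gap_tg <- rules$composition$transgender_sex_gap
  gap_bio <- rules$composition$biological_sex_gap
  sex_of <- function(type) switch(type, Male = "MALE", Female = "FEMALE",
                                  Male_Abbreviation = "MALE", NA_character_)

  # axis-sex pairing is proximity-greedy across both axes, so in
  # "biologically male (not transgendered)" the Biological hit (gap 0)
  # claims "male" before the Transgender hit (gap 2) can
  hit_gap <- function(i, j) {
    if (hits$start[j] > hits$end[i]) hits$start[j] - hits$end[i] - 1L
    else if (hits$start[i] > hits$end[j]) hits$start[i] - hits$end[j] - 1L
    else 0L
  }
  pairs <- list()
  for (i in which(hits$type %in% c("Transgender", "Biological"))) {
    gap <- if (hits$type[i] == "Transgender") gap_tg else gap_bio
    for (j in which(hits$type %in% c("Male", "Female"))) {
      g <- hit_gap(i, j)
      if (g <= gap) {
        pairs[[length(pairs) + 1L]] <- c(i = i, j = j, gap = g)
      }
    }
  }
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, "gap"], pm[, "i"]), , drop = FALSE]
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, "i"]; j <- pm[r, "j"]
      if (used[i] || used[j]) next
      used[c(i, j)] <- TRUE
      prefix <- if (hits$type[i] == "Transgender") "TRANSGENDER" else "BIOLOGICAL"
      ms <- c(ms, min(hits$start[i], hits$start[j]))
      me <- c(me, max(hits$end[i], hits$end[j]))
      mcomp <- c(mcomp, paste0(prefix, "_", sex_of(hits$type[j])))
    }
  }

  for (i in which(!used)) {
    comp <- switch(hits$type[i],
      Transgender = rules$composition$lone_transgender,
      Biological = rules$composition$lone_biological,
      Two_Gender = rules$composition$two_gender,
      Male = "BIOLOGICAL_MALE",
      Male_Abbreviation = "BIOLOGICAL_MALE",
      Female = "BIOLOGICAL_FEMALE",
      NULL)
    if (is.null(comp)) next
    used[i] <- TRUE
    ms <- c(ms, hits$start[i]); me <- c(me, hits$end[i])
    mcomp <- c(mcomp, comp)
  }
  if (length(ms) == 0) return(mention_frame())
  surface <- vapply(seq_along(ms), function(k) {
    paste(tokens[ms[k]:me[k]], collapse = " ")
  }, character(1))
  res <- new_mention(ms, me, surface, mcomp)
  res[order(res$start), , drop = FALSE]
}

#' Verify mentions against partner and negation context
#'
#' Two verification passes, partner first:
#' \enumerate{
#'   \item Partner rule: a mention immediately governed by a `Partner`
#'     feature (the feature starts within `partner_gap` tokens after the
#'     mention) does not describe the target population and becomes
#'     `IRRELEVANT`.
#'   \item Negation rule: a `Negation_Word` feature within the negation
#'     window of a mention flips its polarity to `NEGATED`. A trigger
#'     attaches forward to the nearest following mention inside the window
#'     (the canonical `[Negation_Word] <mention>` shape); only if no
#'     mention follows does it attach backward to the nearest preceding
#'     mention (covering trailing "... will not be excluded"). No other
#'     mention may intervene.
#' }
#'
#' @param mentions Mention frame from [compose_mentions()] (and/or pattern
#'   mentions).
#' @param hits Lexicon hit frame for the same sentence (supplies `Partner`
#'   and `Negation_Word` features).
#' @param rules Rule configuration.
#' @return The mention frame with updated `polarity` and negation trigger
#'   spans.
#' @export
verify_mentions <- function(mentions, hits, rules = default_rules()) {
  if (nrow(mentions) == 0) return(mentions)
  gap <- rules$verification$partner_gap
  win <- rules$verification$negation_window

  partner_starts <- hits$start[hits$type == "Partner"]
  for (ps in partner_starts) {
    gov <- which(mentions$polarity != "IRRELEVANT" &
                   mentions$end < ps & ps - mentions$end - 1L <= gap)
    if (length(gov) > 0) {
      # the nearest mention before the partner feature is partner-governed
      g <- gov[which.max(mentions$end[gov])]
      mentions$polarity[g] <- "IRRELEVANT"
    }
  }

  neg_idx <- which(hits$type == "Negation_Word")
  active <- function() which(mentions$polarity != "IRRELEVANT")
  for (t in neg_idx) {
    ts <- hits$start[t]; te <- hits$end[t]
    idx <- active()
    if (length(idx) == 0) break
    fwd <- idx[mentions$start[idx] > te &
                 mentions$start[idx] - te - 1L <= win]
    tgt <- NA_integer_
    if (length(fwd) > 0) {
      tgt <- fwd[which.min(mentions$start[fwd])]
    } else {
      bwd <- idx[mentions$end[idx] < ts & ts - mentions$end[idx] - 1L <= win]
      if (length(bwd) > 0) {
        tgt <- bwd[which.max(mentions$end[bwd])]
      }
    }
    if (!is.na(tgt) && mentions$polarity[tgt] == "ASSERTED") {
      mentions$polarity[tgt] <- "NEGATED"
      mentions$trigger_start[tgt] <- ts
      mentions$trigger_end[tgt] <- te
    }
  }
  mentions
}

#' Apply inclusion/exclusion section semantics
#'
#' A gender asserted in exclusion criteria excludes that gender: asserted
#' mentions become negated. A negated mention in exclusion ("will not be
#' excluded") is a double negation and becomes asserted. Other sections are
#' untouched; irrelevant mentions stay irrelevant.
#'
#' @param mentions Mention frame.
#' @param section Section name (`"EXCLUSION"` triggers the flip).
#' @return The mention frame with flipped polarities.
#' @export
apply_section_logic <- function(mentions, section) {
  if (!identical(section, "EXCLUSION") || nrow(mentions) == 0) {
    return(mentions)
  }
  pol <- mentions$polarity
  mentions$polarity <- ifelse(pol == "ASSERTED", "NEGATED",
                              ifelse(pol == "NEGATED", "ASSERTED", pol))
  mentions
}

# Type a pattern slot. The slot's own lexicon hits are composed first; the
# pattern context decides how a bare sexed word is read: with an
# assigned-sex-at-birth cue in the context, a context sex word names the
# assigned sex and the slot's gender is its trans_constrain image; a bare
# slot sex word under a birth cue is the identified gender. Without any
# sexed evidence the slot is an unsexed transgender mention.
type_pattern_slot <- function(tokens, slot_start, slot_end, pattern_row,
                              lexicon, rules) {
  slot_toks <- tokens[slot_start:slot_end]
  slot_hits <- match_lexicon_idx(slot_toks, lexicon)
  slot_m <- compose_mentions(slot_hits, slot_toks, rules)
  tg <- slot_m$composite[startsWith(slot_m$composite, "TRANSGENDER")]
  if (length(tg) > 0) return(tg[1])

  ctx_toks <- c(strsplit(pattern_row$left, " ", fixed = TRUE)[[1]],
                strsplit(pattern_row$right, " ", fixed = TRUE)[[1]])
  ctx_toks <- ctx_toks[nzchar(ctx_toks)]
  cues <- rules$slot_typing$birth_cues
  has_cue <- any(ctx_toks %in% cues)
  slot_sex <- slot_m$composite[slot_m$composite %in%
                                 c("BIOLOGICAL_MALE", "BIOLOGICAL_FEMALE")]
  if (has_cue) {
    ctx_hits <- match_lexicon_idx(ctx_toks, lexicon)
    ctx_sex <- ctx_hits$type[ctx_hits$type %in% c("Male", "Female")]
    if (length(ctx_sex) > 0) {
      # context sex is the assigned sex at birth; flip to identified gender
      return(trans_constrain(paste0("BIOLOGICAL_", toupper(ctx_sex[1]))))
    }
    if (length(slot_sex) > 0) {
      # slot sex read as the identified gender
      return(sub("^BIOLOGICAL", "TRANSGENDER", slot_sex[1]))
    }
  }
  "TRANSGENDER_ALL"
}

#' Extract gender mentions from one sentence
#'
#' Pattern matches first (each slot becomes one transgender mention, typed
#' from the slot and pattern context), then heuristic-rule composition over
#' lexicon hits; rule mentions overlapping a pattern slot are dropped
#' unless they agree with it, in which case the mention's provenance is
#' `BOTH`. Verification and section logic close the sentence.
#'
#' @param text Sentence text.
#' @param section Section name (`DESCRIPTION`, `INCLUSION`, `EXCLUSION`,
#'   `OTHER`).
#' @param patterns Optional `pattern_set`.
#' @param lexicon Lexicon ([default_lexicon()]).
#' @param rules Rule configuration ([default_rules()]).
#' @return A mention data frame.
#' @export
extract_sentence <- function(text, section = "OTHER", patterns = NULL,
                             lexicon = default_lexicon(),
                             rules = default_rules()) {
  toks <- tokenize_chr(text)
  if (length(toks) == 0) return(mention_frame())
  hits <- match_lexicon_idx(toks, lexicon)

  pat_m <- mention_frame()
  if (!is.null(patterns)) {
    cp <- compile_patterns(patterns)
    if (length(cp$patterns) > 0) {
      slots <- match_patterns(toks, cp, rules$slot_typing$max_slot_tokens)
      if (nrow(slots) > 0) {
        pat_m <- do.call(rbind, lapply(seq_len(nrow(slots)), function(k) {
          comp <- type_pattern_slot(toks, slots$slot_start[k],
                                    slots$slot_end[k],
                                    cp$set[slots$pattern[k], , drop = FALSE],
                                    lexicon, rules)
          new_mention(slots$slot_start[k], slots$slot_end[k],
                      paste(toks[slots$slot_start[k]:slots$slot_end[k]],
                            collapse = " "),
                      comp, provenance = "PATTERN")
        }))
      }
    }
  }

  rule_m <- compose_mentions(hits, toks, rules)
  if (nrow(pat_m) > 0 && nrow(rule_m) > 0) {
    drop <- logical(nrow(rule_m))
    for (r in seq_len(nrow(rule_m))) {
      for (p in seq_len(nrow(pat_m))) {
        if (rule_m$start[r] <= pat_m$end[p] &&
            rule_m$end[r] >= pat_m$start[p]) {
          if (rule_m$start[r] == pat_m$start[p] &&
              rule_m$end[r] == pat_m$end[p] &&
              rule_m$composite[r] == pat_m$composite[p]) {
            pat_m$provenance[p] <- "BOTH"
          }
          # inside a pattern slot the pattern's reading wins
          drop[r] <- TRUE
        }
      }
    }
    rule_m <- rule_m[!drop, , drop = FALSE]
  }

  mentions <- rbind(pat_m, rule_m)
  if (nrow(mentions) == 0) return(mentions)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  mentions <- verify_mentions(mentions, hits, rules)
  mentions <- apply_section_logic(mentions, section)
  mentions$section <- section
  mentions
}

#' Segment raw eligibility criteria text into sections
#'
#' Case-insensitive header regexes partition the criteria block into
#' inclusion and exclusion parts; text before any header is `OTHER`.
#'
#' @param text Raw criteria text.
#' @param rules Rule configuration (supplies the header regexes).
#' @return A list with elements `other`, `inclusion`, `exclusion`.
#' @export
segment_criteria <- function(text, rules = default_rules()) {
  out <- list(other = "", inclusion = "", exclusion = "")
  if (is.null(text) || is.na(text) || !nzchar(text)) return(out)
  inc <- regexpr(rules$sections$inclusion_header, text, perl = TRUE)
  exc <- regexpr(rules$sections$exclusion_header, text, perl = TRUE)
  marks <- data.frame(kind = c("inclusion", "exclusion"),
                      at = c(inc[1], exc[1]),
                      len = c(attr(inc, "match.length"),
                              attr(exc, "match.length")))
  marks <- marks[marks$at > 0, , drop = FALSE]
  marks <- marks[order(marks$at), , drop = FALSE]
  if (nrow(marks) == 0) {
    out$other <- text
    return(out)
  }
  if (marks$at[1] > 1) out$other <- substr(text, 1, marks$at[1] - 1)
  for (i in seq_len(nrow(marks))) {
    from <- marks$at[i] + marks$len[i]
    to <- if (i < nrow(marks)) marks$at[i + 1] - 1 else nchar(text)
    out[[marks$kind[i]]] <- substr(text, from, to)
  }
  out
}

#' Construct a trial record
#'
#' @param nct_id Registry-style identifier.
#' @param description Study description text.
#' @param inclusion,exclusion Eligibility criteria sections.
#' @param registered_sex Conventional registered sex (`MALE`, `FEMALE`,
#'   `ALL`, `UNKNOWN`).
#' @param gold_label Optional gold 13-type label (for evaluation).
#' @return A list of class `trial_record`.
#' @export
trial_record <- function(nct_id, description = "", inclusion = "",
                         exclusion = "", registered_sex = "UNKNOWN",
                         gold_label = NA_character_) {
  stopifnot(is.character(nct_id), length(nct_id) == 1)
  registered_sex <- toupper(registered_sex)
  if (registered_sex %in% c("BOTH", "ALL SEXES")) registered_sex <- "ALL"
  if (!registered_sex %in% c("MALE", "FEMALE", "ALL", "UNKNOWN")) {
    registered_sex <- "UNKNOWN"
  }
  structure(list(nct_id = nct_id,
                 description = description %||% "",
                 inclusion = inclusion %||% "",
                 exclusion = exclusion %||% "",
                 registered_sex = registered_sex,
                 gold_label = gold_label),
            class = "trial_record")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x

#' Extract all gender mentions from a trial
#'
#' Scans the study description and the inclusion/exclusion criteria
#' sections sentence by sentence: pattern matching, heuristic rule
#' composition, context verification and section logic, in that order.
#' Duplicate detections of the same span and type are merged with
#' provenance `BOTH`. Mentions are returned sorted by (section, sentence,
#' span start).
#'
#' @param trial A [trial_record()] (or a list with the same fields).
#' @param patterns Optional `pattern_set` of learned patterns.
#' @param lexicon Lexicon ([default_lexicon()]).
#' @param rules Rule configuration ([default_rules()]).
#' @return A mention data frame (possibly empty).
#' @export
#' @examples
#' tr <- trial_record("NCT00000001", inclusion = "Inclusion: adult males.")
#' extract_trial(tr)[, c("section", "surface", "composite", "polarity")]
extract_trial <- function(trial, patterns = NULL,
                          lexicon = default_lexicon(),
                          rules = default_rules()) {
  if (!is.list(lexicon) || is.null(lexicon$tables)) {
    lexicon <- compile_lexicon(lexicon)
  }
  if (!is.null(patterns)) patterns <- compile_patterns(patterns)
  sections <- list(DESCRIPTION = trial$description,
                   INCLUSION = trial$inclusion,
                   EXCLUSION = trial$exclusion)
  res <- list()
  for (sec in names(sections)) {
    txt <- sections[[sec]]
    if (is.null(txt) || is.na(txt) || !nzchar(trimws(txt))) next
    sents <- split_sentences(txt, trial_id = trial$nct_id, section = sec)
    for (i in seq_len(nrow(sents))) {
      m <- extract_sentence(sents$text[i], section = sec,
                            patterns = patterns, lexicon = lexicon,
                            rules = rules)
      if (nrow(m) > 0) {
        m$trial_id <- trial$nct_id
        m$sentence_index <- sents$index[i]
        res[[length(res) + 1L]] <- m
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(mention_frame())
  sec_order <- match(out$section, c("DESCRIPTION", "INCLUSION", "EXCLUSION",
                                    "OTHER"))
  out <- out[order(sec_order, out$sentence_index, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write mention frames as JSON lines
#'
#' @param mentions A mention data frame.
#' @param path File path.
#' @export
write_mentions <- function(mentions, path) {
  lines <- vapply(seq_len(nrow(mentions)), function(i) {
    jsonlite::toJSON(as.list(mentions[i, , drop = FALSE]),
                     auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    x <- lapply(x, function(v) if (is.null(v)) NA else v)
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- mention_frame()
  out
}
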