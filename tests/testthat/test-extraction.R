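test_that("lexicon hits are longest-match-first and non-overlapping", {
  h <- match_lexicon(tokenize("men who have sex with men (msm)"))
  expect_identical(h$type[h$surface == "msm"], "Male_Abbreviation")
  expect_equal(sum(h$type == "Male"), 2)

  h2 <- match_lexicon(tokenize("both genders welcome"))
  expect_identical(h2$type, "Two_Gender")
  expect_identical(h2$surface, "both genders")

  expect_equal(nrow(match_lexicon(tokenize("placebo-controlled study"))), 0)
})

test_that("composition rules build typed mentions", {
  compose1 <- function(text) {
    toks <- tokenize(text)$token
    compose_mentions(match_lexicon(toks), toks)
  }
  m <- compose1("Self identify as a transgender woman")
  expect_identical(m$composite, "TRANSGENDER_FEMALE")
  expect_identical(m$surface, "transgender woman")

  expect_identical(compose1("Biologically male")$composite, "BIOLOGICAL_MALE")
  expect_identical(compose1("female transgender persons")$composite,
                   "TRANSGENDER_FEMALE")  # either order composes
  expect_identical(compose1("transgender adults")$composite,
                   "TRANSGENDER_ALL")
  expect_identical(compose1("adult males")$composite, "BIOLOGICAL_MALE")
  expect_identical(compose1("open to all genders")$composite,
                   "BIOLOGICAL_ALL")
})

test_that("printed verification sentences get their printed dispositions", {
  s1 <- extract_sentence("male sex partners", "INCLUSION")
  expect_identical(s1$polarity, "IRRELEVANT")

  s2 <- extract_sentence("Male Patients with female sexual partners",
                         "INCLUSION")
  expect_identical(s2$polarity[s2$composite == "BIOLOGICAL_MALE"], "ASSERTED")
  expect_identical(s2$polarity[s2$composite == "BIOLOGICAL_FEMALE"],
                   "IRRELEVANT")

  s3 <- extract_sentence("Biologically male (not transgendered)", "INCLUSION")
  expect_identical(s3$polarity[s3$composite == "BIOLOGICAL_MALE"], "ASSERTED")
  expect_identical(s3$polarity[s3$composite == "TRANSGENDER_ALL"], "NEGATED")
})

test_that("negation triggers attach forward first, backward as fallback", {
  fw <- extract_sentence("no pregnant women will be enrolled", "INCLUSION")
  expect_identical(fw$polarity, "NEGATED")

  bw <- extract_sentence("transgender participants will not be excluded",
                         "EXCLUSION")
  # negated by the trailing "not", then double-negated by the section
  expect_identical(bw$polarity, "ASSERTED")

  far <- extract_sentence(
    "women are eligible but the study is not about menopause", "INCLUSION")
  expect_identical(far$polarity[far$composite == "BIOLOGICAL_FEMALE"],
                   "ASSERTED")  # trigger outside the window
})

test_that("exclusion section flips polarity, other sections do not", {
  m <- data.frame(polarity = c("ASSERTED", "NEGATED", "IRRELEVANT"))
  out <- apply_section_logic(m, "EXCLUSION")
  expect_identical(out$polarity, c("NEGATED", "ASSERTED", "IRRELEVANT"))
  expect_identical(apply_section_logic(m, "DESCRIPTION")$polarity,
                   m$polarity)
})

test_that("extract_trial runs pattern-first extraction with slot typing", {
  pats <- learn_patterns(birth_corpus(6))
  tr <- trial_record(
    "NCT0000001",
    exclusion = paste("Participants who were female at birth,",
                      "who now identify as male, will not be excluded."))
  m <- extract_trial(tr, patterns = pats)
  tg <- m[m$provenance == "PATTERN", ]
  expect_equal(nrow(tg), 1)
  expect_identical(tg$composite, "TRANSGENDER_MALE")
  expect_identical(tg$polarity, "ASSERTED")
  # the assigned-sex context word is not counted as biological evidence
  expect_identical(m$polarity[m$composite == "BIOLOGICAL_FEMALE"], "NEGATED")
  expect_identical(summarize_gender(m)$label, "Transgender Male")

  # male-at-birth variant types the slot as transgender female
  tr2 <- trial_record(
    "NCT0000002",
    exclusion = paste("Participants who were male at birth,",
                      "who now identify as female, will not be excluded."))
  m2 <- extract_trial(tr2, patterns = pats)
  expect_identical(m2$composite[m2$provenance == "PATTERN"],
                   "TRANSGENDER_FEMALE")
})

test_that("rule and pattern agreement dedups to provenance BOTH", {
  corp <- sprintf(
    "men who have sex with men (msm) and [transgender women|TRANSGENDER_FEMALE] (tg).")
  pats <- learn_patterns(rep(corp, 5), pattern_config())
  expect_gt(nrow(pats), 0)
  tr <- trial_record(
    "NCT0000003",
    inclusion = "thai men who have sex with men (msm) and transgender women (tg).")
  m <- extract_trial(tr, patterns = pats)
  hit <- m[m$surface == "transgender women", ]
  expect_equal(nrow(hit), 1)
  expect_identical(hit$provenance, "BOTH")
  expect_identical(hit$composite, "TRANSGENDER_FEMALE")
})

test_that("a trial with only biological criteria yields one male mention", {
  tr <- trial_record("NCT0000004", inclusion = "Inclusion: adult males.")
  m <- extract_trial(tr)
  expect_equal(nrow(m), 1)
  expect_identical(m$composite, "BIOLOGICAL_MALE")
  expect_identical(m$polarity, "ASSERTED")
  # empty trial: no mentions, no error
  expect_equal(nrow(extract_trial(trial_record("NCT0000005"))), 0)
})

test_that("verification never increases the asserted count; output sorted", {
  fx <- generate_fixtures(fixture_spec(n_positive = 15, n_negative = 10,
                                       noise_mention_rate = 0.5,
                                       negation_rate = 0.5,
                                       partner_rate = 0.5, seed = 5))
  lex <- default_lexicon()
  for (tr in fx$trials[1:15]) {
    for (sec in c("description", "inclusion")) {
      sents <- split_sentences(tr[[sec]])
      for (s in sents$text) {
        toks <- tokenize(s)$token
        hits <- match_lexicon(toks, lex)
        raw <- compose_mentions(hits, toks)
        ver <- verify_mentions(raw, hits)
        expect_lte(sum(ver$polarity == "ASSERTED"),
                   sum(raw$polarity == "ASSERTED"))
      }
    }
    m <- extract_trial(tr)
    if (nrow(m) > 1) {
      key <- order(match(m$section, c("DESCRIPTION", "INCLUSION",
                                      "EXCLUSION", "OTHER")),
                   m$sentence_index, m$start)
      expect_identical(key, seq_len(nrow(m)))
    }
  }
})

test_that("criteria segmentation honors inclusion/exclusion headers", {
  seg <- segment_criteria(paste(
    "Some preamble.",
    "Inclusion Criteria: adult males.",
    "Exclusion Criteria: pregnant women."))
  expect_match(seg$other, "preamble")
  expect_match(seg$inclusion, "adult males")
  expect_match(seg$exclusion, "pregnant women")
  seg2 <- segment_criteria("no headers at all")
  expect_identical(seg2$other, "no headers at all")
  expect_identical(seg2$inclusion, "")
})

test_that("removing the pattern stage only loses mentions", {
  fx <- generate_fixtures(fixture_spec(n_positive = 20, n_negative = 0,
                                       pattern_sentence_rate = 1, seed = 13))
  pats <- learn_patterns(fx$corpus)
  for (tr in fx$trials[1:10]) {
    with_p <- extract_trial(tr, patterns = pats)
    without_p <- extract_trial(tr)
    # every rule mention surviving alongside patterns exists without them,
    # with the same polarity
    rules_kept <- with_p[with_p$provenance == "RULE", ]
    for (r in seq_len(nrow(rules_kept))) {
      twin <- without_p[without_p$section == rules_kept$section[r] &
                          without_p$sentence_index == rules_kept$sentence_index[r] &
                          without_p$start == rules_kept$start[r] &
                          without_p$composite == rules_kept$composite[r], ]
      expect_equal(nrow(twin), 1)
      expect_identical(twin$polarity, rules_kept$polarity[r])
    }
  }
})
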