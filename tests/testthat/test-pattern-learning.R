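test_that("both annotation dialects normalize to tagged spans", {
  tagged <- paste("Participants who were female at birth,",
                  "<TG_Start>who now identify as male<TG_End>,",
                  "will not be excluded.")
  corp <- normalize_annotations(tagged)
  expect_length(corp, 1)
  sp <- corp[[1]]$spans
  expect_equal(nrow(sp), 1)
  expect_identical(
    paste(corp[[1]]$tokens[sp$start:sp$end], collapse = " "),
    "who now identify as male")

  plain <- normalize_annotations("no annotation in this sentence.")
  expect_equal(nrow(plain[[1]]$spans), 0)

  two <- normalize_annotations(
    "includes [transgender women|TRANSGENDER_FEMALE] and [transgender men|TRANSGENDER_MALE] alike.")
  expect_equal(nrow(two[[1]]$spans), 2)
  expect_identical(two[[1]]$spans$label,
                   c("TRANSGENDER_FEMALE", "TRANSGENDER_MALE"))

  expect_error(normalize_annotations("broken <TG_Start>span with no end."),
               "unbalanced")
  expect_error(normalize_annotations("broken [span with no close."),
               "malformed")
})

test_that("candidate window enumeration counts are exact", {
  cfg <- pattern_config(beta = 7)
  # >= 7 tokens each side: (7+1)*(7+1) - 1 = 63 candidates
  wide <- normalize_annotations(paste(
    "w1 w2 w3 w4 w5 w6 w7 w8 [the span|X] y1 y2 y3 y4 y5 y6 y7 y8"))
  cand <- extract_candidates(wide, cfg)
  expect_equal(sum(cand$occurrences), 63)

  # span at sentence start with 3 right tokens: right windows 1..3 only
  edge <- normalize_annotations("[the span|X] y1 y2 y3")
  expect_equal(sum(extract_candidates(edge, cfg)$occurrences), 3)

  # beta = 1 with one token each side: 2*2 - 1 = 3
  one <- normalize_annotations("a [the span|X] b")
  expect_equal(sum(extract_candidates(one, pattern_config(beta = 1))$occurrences), 3)
})

test_that("support and confidence count correct matches per span", {
  # four true contexts and one false context for the same pattern shape,
  # mirroring a known error mode of msm-context patterns
  corp <- normalize_annotations(c(
    "thai men who have sex with men (msm) and [transgender women|TRANSGENDER_FEMALE] (tg).",
    "men who have sex with men (msm) and [transgender women|TRANSGENDER_FEMALE] (tgw).",
    "young men who have sex with men (msm) and [trans women|TRANSGENDER_FEMALE] (tw).",
    "adult men who have sex with men (msm) and [transgender persons|TRANSGENDER_ALL] (tg).",
    "including early injectors, men who have sex with men (msm) and female sex workers (fsw)."))
  cand <- data.frame(left = "with men ( msm ) and", right = "(",
                     occurrences = 4L, stringsAsFactors = FALSE)
  scored <- score_patterns(cand, corp, pattern_config())
  expect_equal(scored$support, 4L)
  expect_equal(scored$confidence, 0.8)
})

test_that("threshold filtering keeps at the boundary and drops below", {
  cfg <- pattern_config(support_threshold = 4, confidence_threshold = 0.7)
  scored <- data.frame(
    left = c("a", "b", "c", "d"), right = c("x", "y", "z", "w"),
    occurrences = 1L,
    support = c(4L, 3L, 10L, 5L),
    confidence = c(0.7, 1.0, 0.5, NA),
    stringsAsFactors = FALSE)
  kept <- filter_patterns(scored, cfg)
  expect_identical(kept$left, "a")  # 3/1.0 below support, 10/0.5 below conf
})

test_that("a planted pattern is recovered exactly and anti-recovered", {
  cfg <- pattern_config()
  # 5 clean spans, no false contexts: confidence exactly 1.0
  clean <- sprintf(
    "participants who were female at birth, [%s|TRANSGENDER_MALE], will not be excluded.",
    c("who now identify as male", "who currently identify as male",
      "who now identifies as male", "now identifying as male",
      "who now live as male"))
  pats <- learn_patterns(clean, cfg)
  key <- pats[pats$left == "female at birth ," & pats$right == ", will not", ]
  expect_equal(nrow(key), 1)
  expect_equal(key$support, 5L)
  expect_equal(key$confidence, 1.0)

  # support below the threshold: the pattern family is filtered out
  few <- learn_patterns(clean[1:3], cfg)
  expect_equal(nrow(few), 0)

  # false contexts push confidence below 0.7: filtered
  noisy <- c(clean, rep(
    "patients who were female at birth, as documented, will not be reimbursed.", 3))
  pats_noisy <- learn_patterns(noisy, cfg)
  expect_false(any(pats_noisy$left == "female at birth ," &
                     pats_noisy$right == ", will"))
})

test_that("raising either threshold never enlarges the pattern set", {
  corp <- birth_corpus(5)
  base <- learn_patterns(corp, pattern_config())
  for (s in c(5, 6)) {
    higher <- learn_patterns(corp, pattern_config(support_threshold = s))
    expect_lte(nrow(higher), nrow(base))
  }
  for (cc in c(0.8, 0.95)) {
    higher <- learn_patterns(corp, pattern_config(confidence_threshold = cc))
    expect_lte(nrow(higher), nrow(base))
  }
})

test_that("learning is deterministic and patterns round-trip via JSONL", {
  corp <- birth_corpus(6)
  p1 <- learn_patterns(corp)
  p2 <- learn_patterns(corp)
  expect_identical(p1, p2)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_patterns(p1, f)
  p3 <- read_patterns(f)
  expect_equal(as.data.frame(p1), as.data.frame(p3))
})

test_that("pattern matching recovers the printed slot and merges overlaps", {
  pats <- learn_patterns(birth_corpus(6))
  toks <- tokenize(paste(
    "participants who are female at birth, who now identify as male,",
    "will not be excluded"))$token
  m <- match_patterns(toks, pats)
  expect_equal(nrow(m), 1)  # overlapping pattern hits merged to one slot
  expect_identical(paste(toks[m$slot_start:m$slot_end], collapse = " "),
                   "who now identify as male")
  expect_gt(length(m$patterns[[1]]), 1)

  none <- match_patterns(tokenize("adult males are eligible")$token, pats)
  expect_equal(nrow(none), 0)
})
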