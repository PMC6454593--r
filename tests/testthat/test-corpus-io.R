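test_that("trial JSONL round-trips and tolerates missing fields", {
  trials <- list(
    trial_record("NCT0000001", description = "A study.",
                 inclusion = "adult males.", exclusion = "pregnant women.",
                 registered_sex = "MALE", gold_label = "Biological"),
    trial_record("NCT0000002", inclusion = "transgender adults."),
    trial_record("NCT0000003"))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_trials(trials, f)
  back <- read_trials(f)
  expect_length(back, 3)
  expect_identical(back[[1]], trials[[1]])
  expect_identical(back[[2]]$exclusion, "")
  expect_identical(back[[3]]$registered_sex, "UNKNOWN")
})

test_that("registry XML maps fields into trial records", {
  xml <- '<?xml version="1.0"?>
  <search_results>
    <clinical_study>
      <id_info><nct_id>NCT0100001</nct_id></id_info>
      <brief_summary><textblock>A study of transgender health.</textblock></brief_summary>
      <detailed_description><textblock>Longer text here.</textblock></detailed_description>
      <eligibility>
        <criteria><textblock>Inclusion Criteria: adult males. Exclusion Criteria: pregnant women.</textblock></criteria>
        <gender>All</gender>
      </eligibility>
    </clinical_study>
    <clinical_study>
      <id_info><nct_id>NCT0100002</nct_id></id_info>
      <eligibility><gender>Female</gender></eligibility>
    </clinical_study>
  </search_results>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  trs <- read_trials(f)
  expect_length(trs, 2)
  expect_identical(trs[[1]]$nct_id, "NCT0100001")
  expect_identical(trs[[1]]$registered_sex, "ALL")
  expect_match(trs[[1]]$description, "transgender health")
  expect_match(trs[[1]]$inclusion, "adult males")
  expect_match(trs[[1]]$exclusion, "pregnant women")
  expect_identical(trs[[2]]$registered_sex, "FEMALE")
})

test_that("annotated corpora round-trip through the bracket dialect", {
  corp_lines <- c(
    sprintf("sentence %d with [transgender women|TRANSGENDER_FEMALE] annotated here.",
            1:50),
    sprintf("plain sentence %d without any annotation.", 1:50))
  f <- withr::local_tempfile(fileext = ".txt")
  norm <- normalize_annotations(corp_lines)
  write_annotations(norm, f)
  back <- read_annotations(f)
  expect_length(back, length(norm))
  for (i in seq_along(norm)) {
    expect_identical(back[[i]]$tokens, norm[[i]]$tokens)
    expect_identical(back[[i]]$spans, norm[[i]]$spans)
  }
  # the tag-pair dialect parses to the printed span
  tg <- normalize_annotations(
    "were female at birth, <TG_Start>who now identify as male<TG_End>, will not")
  sp <- tg[[1]]$spans
  expect_identical(paste(tg[[1]]$tokens[sp$start:sp$end], collapse = " "),
                   "who now identify as male")
  expect_error(normalize_annotations("a [b [c|X] d|Y] e."), "nested|malformed")
})

test_that("fixture generation is deterministic and honors the seed", {
  fx1 <- generate_fixtures(tiny_spec())
  fx2 <- generate_fixtures(tiny_spec())
  expect_identical(fx1, fx2)
  fx3 <- generate_fixtures(fixture_spec(n_positive = 12, n_negative = 20,
                                        seed = 43))
  expect_false(identical(fx1$trials, fx3$trials))
  expect_length(fx1$trials, 32)
  # gold labels live on the records; negatives are Biological
  labs <- vapply(fx1$trials, function(t) t$gold_label, character(1))
  expect_equal(sum(labs == "Biological"), 20)
})

test_that("generator label marginals follow the requested mix", {
  mix <- stats::setNames(c(0.5, 0.3, 0.2),
                         c("Transgender Male", "Transgender Female",
                           "Transgender All"))
  fx <- generate_fixtures(fixture_spec(n_positive = 2000, n_negative = 0,
                                       label_mix = mix, seed = 8,
                                       pattern_sentence_rate = 0))
  labs <- vapply(fx$trials, function(t) t$gold_label, character(1))
  obs <- table(factor(labs, levels = names(mix)))
  p <- stats::chisq.test(obs, p = mix)$p.value
  expect_gt(p, 0.001)
})

test_that("the closed loop recovers every gold label without noise", {
  fx <- generate_fixtures(tiny_spec())
  preds <- vapply(fx$trials, function(tr) {
    summarize_gender(extract_trial(tr),
                     registered_sex = tr$registered_sex)$label
  }, character(1))
  gold <- vapply(fx$trials, function(tr) tr$gold_label, character(1))
  expect_identical(preds, gold)
})

test_that("fixture noise arithmetic mirrors the worked dominance ratios", {
  # a single-tier positive with one injected noise mention: 6 primary vs 1
  # noise, pruned at mu = 5 but kept at mu = 6
  fx <- generate_fixtures(fixture_spec(
    n_positive = 30, n_negative = 0, noise_mention_rate = 1,
    pattern_sentence_rate = 0, seed = 21,
    label_mix = stats::setNames(1, "Transgender Male")))
  tr <- fx$trials[[1]]
  cts <- to_meta_counts(extract_trial(tr))
  expect_equal(unclass(cts)[["TRANSGENDER_MALE"]], 6L)
  expect_equal(sum(unclass(cts) > 0), 2)
  expect_identical(summarize_gender(extract_trial(tr), mu = 5)$label,
                   "Transgender Male")
  expect_false(summarize_gender(extract_trial(tr), mu = 6)$label ==
                 "Transgender Male")
})

test_that("the CLI umbrella wires the stages together", {
  dir <- withr::local_tempdir()
  trials_f <- file.path(dir, "trials.jsonl")
  corpus_f <- file.path(dir, "corpus.txt")
  pats_f <- file.path(dir, "patterns.jsonl")
  ment_f <- file.path(dir, "mentions.jsonl")
  summ_f <- file.path(dir, "summaries.jsonl")
  suppressMessages({
    genx_main(c("gen-fixtures", "--seed", "5", "--positives", "6",
                "--negatives", "4", "--out-trials", trials_f,
                "--out-corpus", corpus_f))
    genx_main(c("learn-patterns", "--corpus", corpus_f, "--out", pats_f))
    genx_main(c("extract", "--trials", trials_f, "--patterns", pats_f,
                "--out", ment_f))
    genx_main(c("summarize", "--mentions", ment_f, "--out", summ_f))
  })
  expect_true(all(file.exists(trials_f, corpus_f, pats_f, ment_f, summ_f)))
  summ <- lapply(readLines(summ_f), jsonlite::fromJSON)
  expect_true(all(vapply(summ, function(s) s$label, character(1)) %in%
                    gender_model_labels()))
})
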