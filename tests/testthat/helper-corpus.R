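# shared in-code fixtures for the test suite

# a clean birth-pattern training corpus: n annotated instances per
# assigned-sex variant plus comma-rich unannotated distractors
birth_corpus <- function(n = 6) {
  slots_m <- c("who now identify as male", "who currently identify as male",
               "who now identifies as male", "now identifying as male",
               "who now identify as men", "who now live as male")
  slots_f <- sub("male", "female", slots_m, fixed = TRUE)
  c(sprintf("participants who were female at birth, [%s|TRANSGENDER_MALE], will not be excluded.",
            rep_len(slots_m, n)),
    sprintf("participants who were male at birth, [%s|TRANSGENDER_FEMALE], will not be excluded.",
            rep_len(slots_f, n)),
    "patients on insulin, or on oral agents, will not be excluded.",
    "adults with hypertension, if controlled, will not be excluded.")
}

tiny_spec <- function(...) {
  fixture_spec(n_positive = 12, n_negative = 20, noise_mention_rate = 0,
               negation_rate = 0, partner_rate = 0,
               pattern_sentence_rate = 0, seed = 42, ...)
}

meta_counts <- function(tg_m = 0, tg_f = 0, bio_m = 0, bio_f = 0) {
  to_meta_counts(c(rep("TRANSGENDER_MALE", tg_m),
                   rep("TRANSGENDER_FEMALE", tg_f),
                   rep("BIOLOGICAL_MALE", bio_m),
                   rep("BIOLOGICAL_FEMALE", bio_f)))
}
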