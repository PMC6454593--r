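#' @title Synthetic trial fixtures
#'
#' @description
#' The gold-standard corpus of transgender-recruiting registry trials is
#' not redistributable, so the package ships a generator that emulates
#' registry-style records with known gold labels: positive trials embed
#' lexicon-expressible gender mention sentences realizing one of the 12
#' transgender-involving model labels (optionally including
#' assigned-at-birth phrasings that only learned patterns can resolve),
#' plus configurable noise, negation and partner distractors; a large pool
#' of non-transgender records reproduces the class imbalance of real
#' registry data. The generator also emits an inline-annotated corpus for
#' pattern learning.
#'
#' Mention counts are fixed by design so the predominance threshold
#' `mu = 5` is the planted optimum: the primary transgender component of a
#' label occurs 5 times against secondary biological components occurring
#' once each (ratio exactly 1/5, kept at `mu = 5`, wrongly pruned at
#' `mu = 4`), while injected noise mentions occur once against a primary
#' count of 6 (ratio 1/6, pruned at `mu = 5`, wrongly kept at `mu = 6`).
#'
#' @name fixtures
NULL

#' Fixture generator specification
#'
#' @param n_positive Number of transgender-recruiting trials (default 134,
#'   the size of a realistic gold standard).
#' @param n_negative Number of non-transgender-recruiting trials (default
#'   5000, reproducing registry-scale class imbalance).
#' @param label_mix Named probability vector over gold labels for the
#'   positives; defaults to uniform over the 12 transgender-involving
#'   labels.
#' @param noise_mention_rate Probability that a (single-tier) positive
#'   trial carries one off-label noise mention.
#' @param negation_rate,partner_rate Probabilities of negation / partner
#'   distractor sentences per trial.
#' @param pattern_sentence_rate Probability that a positive trial with a
#'   single-sex transgender component phrases one of its mentions in the
#'   assigned-at-birth form that only patterns resolve.
#' @param n_pattern_train Annotated training sentences generated per
#'   birth-pattern variant (default 6, comfortably above the support
#'   threshold of 4).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_positive = 134, n_negative = 5000,
                         label_mix = NULL, noise_mention_rate = 0.25,
                         negation_rate = 0.2, partner_rate = 0.2,
                         pattern_sentence_rate = 0.3,
                         n_pattern_train = 6, seed = 1) {
  if (is.null(label_mix)) {
    labs <- setdiff(gender_model_labels(), "Biological")
    label_mix <- stats::setNames(rep(1 / length(labs), length(labs)), labs)
  }
  stopifnot(abs(sum(label_mix) - 1) < 1e-8,
            all(names(label_mix) %in% gender_model_labels()),
            n_positive >= 0, n_negative >= 0,
            noise_mention_rate >= 0, noise_mention_rate <= 1,
            negation_rate >= 0, negation_rate <= 1,
            partner_rate >= 0, partner_rate <= 1,
            pattern_sentence_rate >= 0, pattern_sentence_rate <= 1)
  structure(list(n_positive = n_positive, n_negative = n_negative,
                 label_mix = label_mix,
                 noise_mention_rate = noise_mention_rate,
                 negation_rate = negation_rate, partner_rate = partner_rate,
                 pattern_sentence_rate = pattern_sentence_rate,
                 n_pattern_train = n_pattern_train,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# sentence templates realizing exactly one composite mention each
composite_templates <- function() {
  list(
    TRANSGENDER_MALE = c(
      "self identify as a transgender man",
      "transgender men are eligible for this study",
      "participants must identify as a transgender male"),
    TRANSGENDER_FEMALE = c(
      "self identify as a transgender woman",
      "transgender women are eligible for this study",
      "participants must identify as a transgender female"),
    TRANSGENDER_ALL = c(
      "transgender adults are welcome to enroll",
      "this study recruits transgender individuals",
      "transsexual participants may enroll"),
    BIOLOGICAL_MALE = c(
      "biologically male participants are eligible",
      "adult males are eligible"),
    BIOLOGICAL_FEMALE = c(
      "biologically female participants are eligible",
      "adult females are eligible"),
    BIOLOGICAL_ALL = c(
      "open to participants of all genders",
      "m/f participants are accepted"))
}

filler_sentences <- function() {
  c("this is a randomized controlled study of treatment adherence",
    "participants attend monthly visits over one year",
    "the intervention consists of weekly counseling sessions",
    "laboratory assessments are performed at baseline")
}

# the assigned-at-birth phrasing resolvable only by learned patterns;
# sex_at_birth is the assigned sex, so the mention's gender is its opposite
pattern_sentence <- function(sex_at_birth) {
  sprintf(paste0("participants who were %s at birth, who now identify as ",
                 "%s, will not be excluded"),
          tolower(sex_at_birth),
          if (sex_at_birth == "FEMALE") "male" else "female")
}

negation_distractor <- function() {
  c("no pregnant women will be enrolled in this study",
    "participants must not be men over sixty five years of age")
}

partner_distractor <- function() {
  c("participants with female sexual partners are eligible",
    "participants with male sex partners may join the study")
}

label_components <- function(label) {
  # invert gender_label(): returns list(transgender=, biological=)
  for (t in c("NONE", "MALE", "FEMALE", "ALL")) {
    for (b in c("NONE", "MALE", "FEMALE", "ALL")) {
      if (t == "NONE" && b == "NONE") next
      if (gender_label(gender_type(t, b)) == label &&
          !(t == "NONE" && b != "ALL")) {
        return(list(transgender = t, biological = b))
      }
    }
  }
  if (label == "Biological") return(list(transgender = "NONE",
                                         biological = "ALL"))
  stop("unknown label ", label)
}

label_metas <- function(label) {
  comp <- label_components(label)
  metas <- character(0)
  if (comp$transgender != "NONE") {
    g <- paste0("TRANSGENDER_", comp$transgender)
    metas <- c(metas, if (split_judgement(g)) split_gender(g) else g)
  }
  if (comp$biological != "NONE") {
    g <- paste0("BIOLOGICAL_", comp$biological)
    metas <- c(metas, if (split_judgement(g)) split_gender(g) else g)
  }
  metas
}

generate_positive <- function(id, label, spec, tmpl) {
  comp <- label_components(label)
  tg_comp <- paste0("TRANSGENDER_", comp$transgender)
  two_tier <- comp$biological != "NONE"
  primary_n <- if (two_tier) 5L else 6L

  primary <- sample(tmpl[[tg_comp]], primary_n, replace = TRUE)
  exclusion <- character(0)
  if (comp$transgender %in% c("MALE", "FEMALE") &&
      stats::runif(1) < spec$pattern_sentence_rate) {
    assigned <- if (comp$transgender == "MALE") "FEMALE" else "MALE"
    exclusion <- pattern_sentence(assigned)
    primary <- primary[-1]
  }
  secondary <- if (two_tier) {
    sample(tmpl[[paste0("BIOLOGICAL_", comp$biological)]], 1)
  } else {
    character(0)
  }
  noise <- character(0)
  if (!two_tier && stats::runif(1) < spec$noise_mention_rate) {
    noise_meta <- sample(setdiff(meta_genders(), label_metas(label)), 1)
    noise <- sample(tmpl[[noise_meta]], 1)
  }
  distract <- c(
    if (stats::runif(1) < spec$negation_rate) sample(negation_distractor(), 1),
    if (stats::runif(1) < spec$partner_rate) sample(partner_distractor(), 1))

  n_desc <- min(2L, length(primary))
  desc <- c(sample(filler_sentences(), 1), primary[seq_len(n_desc)], noise)
  incl <- c(if (length(primary) > n_desc) primary[(n_desc + 1):length(primary)],
            secondary, distract, sample(filler_sentences(), 1))
  gt <- gender_type(comp$transgender, comp$biological)
  trial_record(
    nct_id = sprintf("NCTP%07d", id),
    description = paste0(paste(desc, collapse = ". "), "."),
    inclusion = paste0(paste(sample(incl), collapse = ". "), "."),
    exclusion = if (length(exclusion)) paste0(exclusion, ".") else "",
    registered_sex = to_conventional(gt),
    gold_label = label)
}

generate_negative <- function(id, tmpl) {
  sex <- sample(c("MALE", "FEMALE", "ALL"), 1)
  kind <- sample(c("sexed", "none"), 1, prob = c(0.7, 0.3))
  body <- if (kind == "none") {
    character(0)
  } else {
    switch(sex,
           MALE = sample(tmpl$BIOLOGICAL_MALE, 1),
           FEMALE = sample(tmpl$BIOLOGICAL_FEMALE, 1),
           ALL = sample(tmpl$BIOLOGICAL_ALL, 1))
  }
  incl <- c(body, sample(filler_sentences(), 1))
  trial_record(
    nct_id = sprintf("NCTN%07d", id),
    description = paste0(sample(filler_sentences(), 1), "."),
    inclusion = paste0(paste(incl, collapse = ". "), "."),
    registered_sex = sex,
    gold_label = "Biological")
}

# annotated training corpus: n clean instances per birth-pattern variant
# with varied slots, plus unannotated distractors that kill trivially
# general candidates (e.g. a bare ", <TG> ," context) via low confidence
pattern_training_corpus <- function(n_per_variant) {
  slots <- list(
    MALE = c("who now identify as male", "who currently identify as male",
             "who now identifies as male", "now identifying as male",
             "who now identify as men", "who now live as male"),
    FEMALE = c("who now identify as female",
               "who currently identify as female",
               "who now identifies as female", "now identifying as female",
               "who now identify as women", "who now live as female"))
  out <- character(0)
  for (assigned in c("FEMALE", "MALE")) {
    identity <- if (assigned == "FEMALE") "MALE" else "FEMALE"
    lab <- paste0("TRANSGENDER_", identity)
    sl <- rep_len(slots[[identity]], n_per_variant)
    out <- c(out, sprintf(
      "participants who were %s at birth, [%s|%s], will not be excluded.",
      tolower(assigned), sl, lab))
  }
  c(out,
    "participants with diabetes, as diagnosed by a clinician, will not be excluded.",
    "patients on insulin, or on oral agents, will not be excluded.",
    "adults with hypertension, if controlled, will not be excluded.",
    "subjects with asthma, unless severe, will not be excluded.",
    "smokers, after counseling, will not be excluded.",
    "patients with migraine, when stable, will not be excluded.")
}

#' Generate a synthetic labelled trial corpus
#'
#' @param spec A [fixture_spec()].
#' @return A list: `trials` (list of [trial_record()]s, positives first),
#'   `corpus` (character vector of inline-annotated sentences for pattern
#'   learning), `spec`.
#' @export
#' @examples
#' fx <- generate_fixtures(fixture_spec(n_positive = 5, n_negative = 10))
#' length(fx$trials)
generate_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  tmpl <- composite_templates()
  for (lab in names(spec$label_mix)) {
    comps <- label_components(lab)  # errors on an unknown label
  }
  with_seed(spec$seed, {
    labels <- sample(names(spec$label_mix), spec$n_positive, replace = TRUE,
                     prob = spec$label_mix)
    pos <- lapply(seq_len(spec$n_positive), function(i) {
      generate_positive(i, labels[i], spec, tmpl)
    })
    neg <- lapply(seq_len(spec$n_negative), function(i) {
      generate_negative(i, tmpl)
    })
    list(trials = c(pos, neg),
         corpus = pattern_training_corpus(spec$n_pattern_train),
         spec = spec)
  })
}
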