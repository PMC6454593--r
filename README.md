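# trialgender

Extraction and summarization of gender requirements — in particular
**transgender recruitment requirements** — from unstructured clinical trial
registry text.

## The problem

Clinical trial registries record a study's sex eligibility as one of
`Male`, `Female` or `All`. Trials that recruit transgender participants
cannot express that requirement in the structured field, so it lives only
in free text ("*Identify as a transgender woman (assigned male at birth and
currently identify as female)*") — and the structured field is then often
registered wrongly. For anyone searching or prescreening trials for
transgender participants, the structured data is unreliable and the free
text is unparsed.

`trialgender` is for clinical NLP researchers and trial-search builders who
need that free-text requirement back as structured data. It implements:

1. **A 13-type virtual gender model.** A requirement is a pair
   *(transgender component, biological component)*, each `MALE`, `FEMALE`,
   `ALL` or absent. All purely biological requirements collapse into the
   single type `Biological`, giving 3 × 4 + 1 = 13 labels such as
   `Transgender All, Biological Male`. Evidence is carried by four *meta
   gender types* (transgender male/female, biological male/female); the
   model's judgement functions (`split_judgement()`, `sub_judgement()`, …)
   and transformations (`split_gender()`, `merge_gender()`,
   `trans_constrain()`) relate them.
2. **Mention extraction** (`extract_trial()`): a lexicon of gender mention
   features (Male, Female, Two_Gender, Biological, Transgender,
   Male_Abbreviation, Partner, Negation_Word) with adjacency composition
   rules, context verification (partner-governed mentions become
   irrelevant, negated mentions flip polarity), and inclusion/exclusion
   section logic (a gender asserted in exclusion criteria is a negated
   requirement).
3. **Windowed pattern learning** (`learn_patterns()`): phrasings with no
   transgender keyword ("*female at birth, who now identify as male*") are
   caught by literal token-context patterns learned from an annotated
   corpus. All left/right context windows up to β = 7 tokens per side of an
   annotated span become candidates; candidates are matched back and kept
   when support (correct matches) ≥ ∂_S = 4 and confidence
   (correct / all matches) ≥ ∂_C = 0.7.
4. **Majority-rule summarization** (`summarize_gender()`): asserted
   mentions are split into meta-gender frequencies MG₁ ≥ MG₂ ≥ … and
   scanned with the predominance score

   Pred = (MG\_{i+1} / MG\_i) × μ,   default μ = 5.

   At the first rank where Pred < 1, everything below is noise; the kept
   types merge into the final label, mapped back to the conventional
   `Male`/`Female`/`All` registry option.
5. **Macro-averaged evaluation** (`evaluate_pipeline()`, `macro_metrics()`,
   `tune_mu()`): per-class one-vs-rest precision/recall, macro averages
   with equal class weights (macro F₁ is the harmonic mean of macro P and
   macro R), stratified k-fold cross-validation and μ-grid tuning.
6. **A synthetic fixture generator** (`generate_fixtures()`): registry-like
   trial records with known gold labels and an annotated pattern-learning
   corpus, so the whole pipeline is testable without external data.

## Worked example

Learn the "assigned at birth" pattern from a tiny annotated corpus, then
extract and summarize a trial:

```r
library(trialgender)

corpus <- c(
  sprintf("participants who were female at birth, [%s|TRANSGENDER_MALE], will not be excluded.",
          c("who now identify as male", "who currently identify as male",
            "who now identifies as male", "now identifying as male",
            "who now live as male")),
  "patients on insulin, or on oral agents, will not be excluded.",
  "adults with hypertension, if controlled, will not be excluded.")
pats <- learn_patterns(corpus)

tr <- trial_record(
  "NCT0000123",
  description = "A sexual health study among transgender men.",
  inclusion   = "Inclusion Criteria: self identify as a transgender man. Male sex partners may attend visits.",
  exclusion   = "Participants who were female at birth, who now identify as male, will not be excluded.")
m <- extract_trial(tr, patterns = pats)
m[, c("section", "surface", "composite", "polarity", "provenance")]
#>       section                  surface         composite   polarity provenance
#> 1 DESCRIPTION          transgender men  TRANSGENDER_MALE   ASSERTED       RULE
#> 2   INCLUSION          transgender man  TRANSGENDER_MALE   ASSERTED       RULE
#> 3   INCLUSION                     male   BIOLOGICAL_MALE IRRELEVANT       RULE
#> 4   EXCLUSION                   female BIOLOGICAL_FEMALE    NEGATED       RULE
#> 5   EXCLUSION who now identify as male  TRANSGENDER_MALE   ASSERTED    PATTERN
```

Line 3 is partner-governed ("male **sex partners**") and does not describe
the target population; line 4 is the assigned-sex context word, negated by
the exclusion logic; line 5 is the pattern hit, typed transgender male from
its "female at birth" context and double-negated ("will **not** be
excluded" inside exclusion criteria) back to asserted.

Summarizing a trial whose valid mentions are Transgender Male ×10,
Transgender All ×2, Biological Male ×2, Biological Female ×1:

```r
mentions <- c(rep("TRANSGENDER_MALE", 10), rep("TRANSGENDER_ALL", 2),
              rep("BIOLOGICAL_MALE", 2), "BIOLOGICAL_FEMALE")
counts <- to_meta_counts(mentions)
unclass(counts)
#>   TRANSGENDER_MALE TRANSGENDER_FEMALE    BIOLOGICAL_MALE  BIOLOGICAL_FEMALE
#>                 12                  2                  2                  1
pred_score(counts, 1, mu = 5)
#> [1] 0.8333333
summarize_gender(mentions, mu = 5)
#> <gender_summary> Transgender Male (conventional: MALE)
#>  counts: TRANSGENDER_MALE=12 TRANSGENDER_FEMALE=2 BIOLOGICAL_MALE=2 BIOLOGICAL_FEMALE=1
```

The two `Transgender All` mentions split into one count for each identity
(12 and 2); Pred at the top rank is (2/12) × 5 ≈ 0.83 < 1, so everything
below rank 1 is pruned and the trial summarizes to `Transgender Male`.

## Command line

```sh
GENX=$(Rscript -e 'cat(system.file("cli/genx.R", package = "trialgender"))')
Rscript $GENX gen-fixtures   --seed 7 --positives 134 --negatives 5000 \
        --out-trials trials.jsonl --out-corpus corpus.txt
Rscript $GENX learn-patterns --corpus corpus.txt --out patterns.jsonl
Rscript $GENX extract        --trials trials.jsonl --patterns patterns.jsonl --out mentions.jsonl
Rscript $GENX summarize      --mentions mentions.jsonl --mu 5 --out summaries.jsonl
Rscript $GENX evaluate       --trials trials.jsonl --patterns patterns.jsonl --out eval.json
```

## Documentation

The methods vignette (`vignettes/trialgender-methods.Rmd`) documents the
model, every tunable parameter, what the synthetic generator does and does
not emulate, and the design decisions taken where the published description
leaves room.
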