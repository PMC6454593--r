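#' @title Frequency-based gender requirement summarization
#'
#' @description
#' A trial's verified mentions are reduced to a frequency table over the
#' four meta gender types (splittable `*_ALL` composites contribute one
#' count to each member), ranked in descending order, and pruned by a
#' majority rule: scanning down the ranking, the predominance score
#' `Pred = MG[i+1] / MG[i] * mu` is computed between consecutive ranks, and
#' at the first rank where `Pred < 1` everything below is treated as noise.
#' The kept meta genders are merged back into one of the 13 model labels.
#'
#' @name summarization
NULL

#' Meta gender frequency counts for a set of mentions
#'
#' Only `ASSERTED` mentions count as evidence: negated mentions assert who
#' is *not* recruited and irrelevant mentions (partner-governed) describe
#' someone else. Splittable composites (`TRANSGENDER_ALL`,
#' `BIOLOGICAL_ALL`) contribute one count to each of their two members.
#'
#' @param mentions A mention data frame (see [extract_trial()]), or a
#'   character vector of composite labels (all treated as asserted).
#' @return A named integer vector over [meta_genders()], class
#'   `meta_gender_counts`.
#' @export
#' @examples
#' to_meta_counts(c(rep("TRANSGENDER_MALE", 10), rep("TRANSGENDER_ALL", 2),
#'                  rep("BIOLOGICAL_MALE", 2), "BIOLOGICAL_FEMALE"))
to_meta_counts <- function(mentions) {
  if (is.data.frame(mentions)) {
    comp <- mentions$composite[mentions$polarity == "ASSERTED"]
  } else {
    comp <- as.character(mentions)
  }
  counts <- stats::setNames(integer(4), meta_genders())
  if (length(comp) > 0) {
    assert_composite(comp)
    split_mask <- split_judgement(comp)
    metas <- c(comp[!split_mask],
               unlist(lapply(comp[split_mask], split_gender)))
    tab <- table(factor(metas, levels = meta_genders()))
    counts[] <- as.integer(tab)
  }
  class(counts) <- "meta_gender_counts"
  counts
}

# descending ranking with the canonical meta-gender order breaking ties.
# Ties can never straddle a prune boundary: at a tie the Pred score equals
# mu >= 1, which is never < 1, so the tie-break order is cosmetic.
rank_counts <- function(counts) {
  counts <- unclass(counts)
  ord <- order(-counts, match(names(counts), meta_genders()))
  counts[ord]
}

#' Predominance score between consecutive ranks
#'
#' `pred_score(counts, i, mu)` returns `MG[i+1] / MG[i] * mu` over the
#' descending ranking of `counts`. If the score is below 1 the summarizer
#' treats every type ranked below `i` as noise.
#'
#' @param counts Meta gender counts (see [to_meta_counts()]).
#' @param i Rank index (1-based; ranks `i` and `i + 1` must exist).
#' @param mu Predominance threshold (default 5).
#' @return A single number.
#' @export
#' @examples
#' pred_score(to_meta_counts(c(rep("TRANSGENDER_MALE", 12),
#'                             rep("TRANSGENDER_FEMALE", 2))), 1)  # 5/6
pred_score <- function(counts, i, mu = 5) {
  ranked <- rank_counts(counts)
  stopifnot(i >= 1, i + 1 <= length(ranked))
  if (ranked[i] == 0) {
    stop("Pred is undefined at a zero-count rank", call. = FALSE)
  }
  unname(ranked[i + 1] / ranked[i] * mu)
}

#' Prune noise meta gender types by the majority rule
#'
#' Scans the descending ranking; at the first rank `i` where
#' `pred_score(counts, i, mu) < 1`, ranks `1..i` are kept and the rest
#' pruned. If no boundary is found all nonzero ranks are kept. Zero-count
#' types are always pruned.
#'
#' @param counts Meta gender counts with at least one nonzero entry.
#' @param mu Predominance threshold (default 5).
#' @return A list with character vectors `kept` and `pruned`.
#' @export
#' @examples
#' prune_noise(to_meta_counts(c(rep("TRANSGENDER_MALE", 12),
#'   rep("TRANSGENDER_FEMALE", 2), rep("BIOLOGICAL_MALE", 2),
#'   "BIOLOGICAL_FEMALE")))
prune_noise <- function(counts, mu = 5) {
  stopifnot(mu > 0)
  ranked <- rank_counts(counts)
  nz <- sum(ranked > 0)
  if (nz == 0) {
    stop("cannot prune with no evidence (all counts zero)", call. = FALSE)
  }
  keep_n <- nz
  for (i in seq_len(nz - 1)) {
    if (ranked[i + 1] / ranked[i] * mu < 1) {
      keep_n <- i
      break
    }
  }
  list(kept = names(ranked)[seq_len(keep_n)],
       pruned = setdiff(names(ranked), names(ranked)[seq_len(keep_n)]))
}

#' Summarize meta gender counts into a gender requirement
#'
#' The core of the summarization stage, shared by [summarize_gender()] and
#' the evaluation harness (which re-summarizes cached counts at many
#' thresholds): prune, compose the kept set into a model label, map to the
#' conventional registry option. With all-zero counts the fallback summary
#' is the collapsed `"Biological"` type at the trial's registered sex
#' (`ALL` when unknown), flagged `fallback = TRUE`.
#'
#' @param counts Meta gender counts.
#' @param mu Predominance threshold (default 5).
#' @param registered_sex Conventional registered sex used by the fallback.
#' @param conventional_by Mapping direction for [to_conventional()].
#' @return A `gender_summary` list: `label`, `gender_type`, `conventional`,
#'   `kept`, `pruned`, `counts`, `fallback`.
#' @export
summarize_counts <- function(counts, mu = 5, registered_sex = "UNKNOWN",
                             conventional_by = "identity") {
  if (sum(unclass(counts)) == 0) {
    sex <- if (registered_sex %in% c("MALE", "FEMALE")) registered_sex else "ALL"
    gt <- gender_type("NONE", sex)
    return(structure(list(label = gender_label(gt), gender_type = gt,
                          conventional = to_conventional(gt, conventional_by),
                          kept = character(0), pruned = character(0),
                          counts = counts, fallback = TRUE),
                     class = "gender_summary"))
  }
  pr <- prune_noise(counts, mu)
  gt <- compose_label(pr$kept)
  structure(list(label = gender_label(gt), gender_type = gt,
                 conventional = to_conventional(gt, conventional_by),
                 kept = pr$kept, pruned = pr$pruned, counts = counts,
                 fallback = FALSE),
            class = "gender_summary")
}

#' Summarize a trial's mentions into its final gender requirement
#'
#' @param mentions A mention data frame from [extract_trial()], or a
#'   character vector of asserted composite labels.
#' @param mu Predominance threshold (default 5).
#' @param registered_sex Registered sex used when no asserted mention
#'   exists (fallback).
#' @param conventional_by Mapping direction for [to_conventional()].
#' @return A `gender_summary` (see [summarize_counts()]); the negated
#'   evidence is attached as `negated` for audit.
#' @export
#' @examples
#' m <- c(rep("TRANSGENDER_MALE", 10), rep("TRANSGENDER_ALL", 2),
#'        rep("BIOLOGICAL_MALE", 2), "BIOLOGICAL_FEMALE")
#' summarize_gender(m)$label  # "Transgender Male"
summarize_gender <- function(mentions, mu = 5, registered_sex = "UNKNOWN",
                             conventional_by = "identity") {
  counts <- to_meta_counts(mentions)
  out <- summarize_counts(counts, mu = mu, registered_sex = registered_sex,
                          conventional_by = conventional_by)
  if (is.data.frame(mentions)) {
    out$negated <- mentions$composite[mentions$polarity == "NEGATED"]
  } else {
    out$negated <- character(0)
  }
  out
}

#' @export
print.gender_summary <- function(x, ...) {
  cat("<gender_summary> ", x$label, " (conventional: ", x$conventional, ")\n",
      sep = "")
  cts <- unclass(x$counts)
  cat(" counts:", paste(names(cts), cts, sep = "=", collapse = " "), "\n")
  if (x$fallback) cat(" fallback: no asserted gender evidence\n")
  invisible(x)
}

#' Summarize many trials
#'
#' @param mention_list A list of mention data frames (one per trial).
#' @param mu Predominance threshold.
#' @param registered_sex Character vector of registered sexes (recycled).
#' @return A data frame with one row per trial: `label`, `conventional`,
#'   `fallback`.
#' @export
summarize_trials <- function(mention_list, mu = 5,
                             registered_sex = "UNKNOWN") {
  n <- length(mention_list)
  registered_sex <- rep_len(registered_sex, n)
  rows <- lapply(seq_len(n), function(i) {
    s <- summarize_gender(mention_list[[i]], mu = mu,
                          registered_sex = registered_sex[i])
    data.frame(label = s$label, conventional = s$conventional,
               fallback = s$fallback, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
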