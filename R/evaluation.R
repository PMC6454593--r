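#' @title Macro-averaged multi-class evaluation
#'
#' @description
#' Gender requirement summarization is evaluated as a multi-classification
#' task over the 13 model labels. Because non-transgender-recruiting trials
#' vastly outnumber transgender-recruiting ones, macro-averaged metrics --
#' which weight every class equally -- are the headline numbers: macro
#' precision and recall are unweighted means of the per-class one-vs-rest
#' values, and the macro F1 is the harmonic mean of macro precision and
#' macro recall (not the mean of per-class F1 values).
#'
#' @name evaluation
NULL

#' Build a multi-class confusion matrix
#'
#' @param gold,pred Character vectors of gold and predicted labels.
#' @param classes Ordered class list; defaults to the union of observed
#'   labels.
#' @return A square integer matrix (rows = gold, cols = predicted) of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(gold, pred, classes = NULL) {
  stopifnot(length(gold) == length(pred))
  if (is.null(classes)) classes <- sort(unique(c(gold, pred)))
  m <- table(factor(gold, levels = classes), factor(pred, levels = classes))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(gold = classes, pred = classes)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Per-class one-vs-rest precision, recall and F-measure
#'
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`, and the
#' F-measure `(1 + beta^2) * P * R / (beta^2 * P + R)`. By the default
#' convention a class with an undefined ratio (0/0) scores 0; set
#' `zero_division = NA` to propagate NA instead.
#'
#' @param cm A [confusion_matrix()].
#' @param class Class label.
#' @param beta F-measure weight (default 1).
#' @param zero_division Value for 0/0 (default 0).
#' @return Named numeric vector `precision`, `recall`, `f`.
#' @export
per_class_metrics <- function(cm, class, beta = 1, zero_division = 0) {
  classes <- rownames(cm)
  if (!class %in% classes) stop("unknown class '", class, "'", call. = FALSE)
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  p <- if (tp + fp == 0) zero_division else tp / (tp + fp)
  r <- if (tp + fn == 0) zero_division else tp / (tp + fn)
  f <- if (is.na(p) || is.na(r) || (beta^2 * p + r) == 0) {
    if (is.na(p) || is.na(r)) zero_division else 0
  } else {
    (1 + beta^2) * p * r / (beta^2 * p + r)
  }
  c(precision = p, recall = r, f = f)
}

#' Macro-averaged metrics over all classes
#'
#' Macro precision and recall are unweighted means over the `n` classes;
#' macro F1 is `2 * P_macro * R_macro / (P_macro + R_macro)`.
#'
#' @param cm A [confusion_matrix()].
#' @param beta Per-class F-measure weight (reported per class; the macro F
#'   always uses the harmonic-mean-of-macro form).
#' @param zero_division Per-class 0/0 convention (see
#'   [per_class_metrics()]); with the default 0, absent classes count as 0
#'   in the macro average.
#' @return A list of class `eval_report`: `per_class` (data frame),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n_classes`.
#' @export
macro_metrics <- function(cm, beta = 1, zero_division = 0) {
  classes <- rownames(cm)
  if (length(classes) == 0 || sum(cm) == 0) {
    stop("empty confusion matrix", call. = FALSE)
  }
  per <- t(vapply(classes, function(cl) {
    per_class_metrics(cm, cl, beta = beta, zero_division = zero_division)
  }, c(precision = 0, recall = 0, f = 0)))
  per <- data.frame(class = classes, per, row.names = NULL,
                    stringsAsFactors = FALSE)
  mp <- mean(per$precision)
  mr <- mean(per$recall)
  mf <- if ((mp + mr) == 0) 0 else 2 * mp * mr / (mp + mr)
  structure(list(per_class = per, macro_precision = mp, macro_recall = mr,
                 macro_f1 = mf, n_classes = length(classes), beta = beta),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d classes | macro P %.3f | macro R %.3f | macro F1 %.3f\n",
    x$n_classes, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' Bootstrap-resample the positive trial set
#'
#' Draws trials with replacement until the resample reaches the size of the
#' input, each draw a copy carrying its annotations -- the construction of
#' the training pool used for pattern learning.
#'
#' @param tg A list (or data frame) of positive trial records.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A list/data frame of the same size sampled with replacement.
#' @export
bootstrap_tg <- function(tg, seed = NULL) {
  n <- if (is.data.frame(tg)) nrow(tg) else length(tg)
  if (n == 0) stop("cannot bootstrap an empty trial set", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  if (is.data.frame(tg)) tg[idx, , drop = FALSE] else tg[idx]
}

# run code under a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Combine positives with sampled negatives into a labelled dataset
#'
#' @param tg List of positive (transgender-recruiting) trial records with
#'   gold labels.
#' @param negatives List of non-transgender-recruiting trial records;
#'   their gold label is forced to `"Biological"`.
#' @param n_neg Number of negatives to sample (without replacement).
#' @param seed Optional integer seed.
#' @return A list of trial records, positives first.
#' @export
build_dataset <- function(tg, negatives, n_neg = length(negatives),
                          seed = NULL) {
  if (n_neg > length(negatives)) {
    stop("requested ", n_neg, " negatives but only ", length(negatives),
         " available", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(length(negatives), n_neg))
  neg <- lapply(negatives[idx], function(tr) {
    tr$gold_label <- "Biological"
    tr
  })
  c(tg, neg)
}

#' Stratified k-fold assignment
#'
#' Folds are disjoint, cover the data, differ in size by at most one, and
#' are stratified by label so minority classes appear in as many folds as
#' their size allows.
#'
#' @param labels Character vector of gold labels.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return An integer vector of fold ids in `1..k`.
#' @export
kfold_split <- function(labels, k = 10, seed = NULL) {
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  with_seed(seed, {
    ord <- order(labels, stats::runif(n))  # shuffle within label groups
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(k), n)
    fold
  })
}

#' Tune the predominance threshold by cross-validation
#'
#' For each fold, macro F1 is computed on the training portion (the other
#' k-1 folds) at every candidate threshold; the per-round winner is the
#' argmax (smallest value on ties) and the global choice is the modal
#' per-round winner (again smallest on ties).
#'
#' @param counts_list List of per-trial meta gender counts (cached from
#'   extraction, so the scan over thresholds is cheap).
#' @param gold Character vector of gold 13-type labels.
#' @param registered_sex Registered sexes for the zero-evidence fallback
#'   (recycled).
#' @param mu_grid Candidate thresholds (default `1:10`).
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed for the fold split.
#' @return A list: `mu` (global choice), `per_round` (data frame of round,
#'   chosen mu, best F1), `f1_grid` (rounds x grid matrix).
#' @export
tune_mu <- function(counts_list, gold, registered_sex = "UNKNOWN",
                    mu_grid = 1:10, k = 10, seed = NULL) {
  n <- length(counts_list)
  stopifnot(length(gold) == n)
  registered_sex <- rep_len(registered_sex, n)
  fold <- kfold_split(gold, k = k, seed = seed)
  classes <- sort(unique(gold))
  # labels at each mu, computed once for all trials
  label_at <- vapply(mu_grid, function(mu) {
    vapply(seq_len(n), function(i) {
      summarize_counts(counts_list[[i]], mu = mu,
                       registered_sex = registered_sex[i])$label
    }, character(1))
  }, character(n))
  f1_grid <- matrix(NA_real_, nrow = k, ncol = length(mu_grid),
                    dimnames = list(paste0("round", seq_len(k)), mu_grid))
  for (r in seq_len(k)) {
    train <- fold != r
    for (m in seq_along(mu_grid)) {
      cm <- confusion_matrix(gold[train], label_at[train, m], classes)
      f1_grid[r, m] <- macro_metrics(cm)$macro_f1
    }
  }
  winner <- apply(f1_grid, 1, function(row) mu_grid[which.max(row)])
  per_round <- data.frame(round = seq_len(k), mu = winner,
                          f1 = apply(f1_grid, 1, max))
  tab <- table(winner)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  list(mu = min(modal), per_round = per_round, f1_grid = f1_grid)
}

#' Run the full pipeline over a dataset and evaluate it
#'
#' Extracts mentions for every trial (patterns + rules), caches the meta
#' gender counts, summarizes at the given threshold and scores the
#' predictions against the gold labels with macro-averaged metrics.
#'
#' @param trials List of [trial_record()]s with gold labels.
#' @param patterns Optional learned `pattern_set`.
#' @param mu Predominance threshold (default 5).
#' @param lexicon,rules Extraction configuration.
#' @param classes Label set for the confusion matrix (defaults to labels
#'   observed in gold and predictions).
#' @return A list: `report` (an `eval_report`), `predictions` (data
#'   frame), `counts_list` (cached per-trial meta counts, reusable by
#'   [tune_mu()]).
#' @export
evaluate_pipeline <- function(trials, patterns = NULL, mu = 5,
                              lexicon = default_lexicon(),
                              rules = default_rules(), classes = NULL) {
  if (!is.list(lexicon) || is.null(lexicon$tables)) {
    lexicon <- compile_lexicon(lexicon)
  }
  if (!is.null(patterns)) patterns <- compile_patterns(patterns)
  counts_list <- vector("list", length(trials))
  pred <- character(length(trials))
  gold <- vapply(trials, function(tr) tr$gold_label, character(1))
  rsex <- vapply(trials, function(tr) tr$registered_sex, character(1))
  for (i in seq_along(trials)) {
    m <- extract_trial(trials[[i]], patterns = patterns, lexicon = lexicon,
                       rules = rules)
    counts_list[[i]] <- to_meta_counts(m)
    pred[i] <- summarize_counts(counts_list[[i]], mu = mu,
                                registered_sex = rsex[i])$label
  }
  cm <- confusion_matrix(gold, pred, classes)
  list(report = macro_metrics(cm),
       predictions = data.frame(
         nct_id = vapply(trials, function(tr) tr$nct_id, character(1)),
         gold = gold, pred = pred, stringsAsFactors = FALSE),
       counts_list = counts_list,
       confusion = cm)
}
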