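#' @title Trial record and annotated corpus I/O
#'
#' @description
#' Readers and writers for the formats the pipeline consumes: a canonical
#' JSONL trial schema (`nct_id`, `description`, `inclusion`, `exclusion`,
#' `registered_sex`, optional `gold_label`), the legacy public registry XML
#' dialect (`<clinical_study>` documents), plain-text directories, and the
#' inline-annotated corpus dialect used for pattern learning.
#'
#' @name corpus_io
NULL

#' Read trial records
#'
#' @param path A file (JSONL, registry XML) or directory (plain text, one
#'   `.txt` per trial, criteria sectioned by headers).
#' @param format `"JSONL"`, `"REGISTRY_XML"` or `"PLAIN_DIR"`; guessed
#'   from the path by default.
#' @param rules Rule configuration (header regexes used to segment raw
#'   criteria blocks).
#' @return A list of [trial_record()]s.
#' @export
read_trials <- function(path, format = c("GUESS", "JSONL", "REGISTRY_XML",
                                         "PLAIN_DIR"),
                        rules = default_rules()) {
  format <- match.arg(format)
  if (format == "GUESS") {
    format <- if (dir.exists(path)) {
      "PLAIN_DIR"
    } else if (grepl("\\.xml$", path, ignore.case = TRUE)) {
      "REGISTRY_XML"
    } else {
      "JSONL"
    }
  }
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  out <- switch(format,
                JSONL = read_trials_jsonl(path),
                REGISTRY_XML = read_trials_xml(path, rules),
                PLAIN_DIR = read_trials_dir(path, rules))
  if (length(out) == 0) {
    stop("no parseable trial records in ", path, call. = FALSE)
  }
  out
}

read_trials_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(x) || is.null(x$nct_id)) {
      warning("skipping malformed record at line ", i, call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- trial_record(
      nct_id = x$nct_id,
      description = x$description %||% "",
      inclusion = x$inclusion %||% "",
      exclusion = x$exclusion %||% "",
      registered_sex = x$registered_sex %||% "UNKNOWN",
      gold_label = x$gold_label %||% NA_character_)
  }
  out
}

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) "" else trimws(xml2::xml_text(hit))
}

read_trials_xml <- function(path, rules = default_rules()) {
  doc <- xml2::read_xml(path)
  studies <- xml2::xml_find_all(doc, "//clinical_study")
  if (length(studies) == 0 && xml2::xml_name(doc) == "clinical_study") {
    studies <- list(doc)
  }
  out <- list()
  for (st in studies) {
    id <- xml_text1(st, ".//id_info/nct_id")
    if (!nzchar(id)) {
      warning("skipping study without nct_id", call. = FALSE)
      next
    }
    descr <- paste(
      xml_text1(st, ".//brief_summary/textblock"),
      xml_text1(st, ".//detailed_description/textblock"))
    crit <- xml_text1(st, ".//eligibility/criteria/textblock")
    seg <- segment_criteria(crit, rules)
    sex <- xml_text1(st, ".//eligibility/gender")
    out[[length(out) + 1L]] <- trial_record(
      nct_id = id, description = trimws(descr),
      inclusion = paste(seg$other, seg$inclusion),
      exclusion = seg$exclusion,
      registered_sex = if (nzchar(sex)) sex else "UNKNOWN")
  }
  out
}

read_trials_dir <- function(path, rules = default_rules()) {
  files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  lapply(files, function(f) {
    txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
    seg <- segment_criteria(txt, rules)
    trial_record(nct_id = tools::file_path_sans_ext(basename(f)),
                 description = seg$other, inclusion = seg$inclusion,
                 exclusion = seg$exclusion)
  })
}

#' Write trial records as JSONL
#'
#' @param trials List of [trial_record()]s.
#' @param path Output file.
#' @export
write_trials <- function(trials, path) {
  lines <- vapply(trials, function(tr) {
    jsonlite::toJSON(unclass(tr), auto_unbox = TRUE, digits = NA,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write annotated corpora
#'
#' One annotated sentence per line in the inline bracket dialect
#' `[span text|LABEL]`; `read_annotations()` also accepts the raw
#' `<TG_Start>...<TG_End>` tag dialect. Writing then reading a corpus
#' reproduces it exactly.
#'
#' @param corpus For writing: a character vector of annotated lines, or a
#'   normalized corpus from [normalize_annotations()].
#' @param path File path.
#' @return `read_annotations()` returns the normalized corpus (a list of
#'   annotated sentences).
#' @export
write_annotations <- function(corpus, path) {
  if (is.list(corpus) && !is.null(corpus[[1]]$tokens)) {
    corpus <- vapply(corpus, render_annotated_sentence, character(1))
  }
  writeLines(corpus, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  normalize_annotations(lines[nzchar(trimws(lines))])
}

# rebuild the bracket dialect from a normalized sentence (token-joined; used
# for round-tripping generated corpora, which are single-spaced)
render_annotated_sentence <- function(sent) {
  toks <- sent$tokens
  sp <- sent$spans
  if (nrow(sp) == 0) return(paste(toks, collapse = " "))
  sp <- sp[order(sp$start), , drop = FALSE]
  parts <- character(0)
  pos <- 1L
  for (k in seq_len(nrow(sp))) {
    if (sp$start[k] > pos) {
      parts <- c(parts, toks[pos:(sp$start[k] - 1L)])
    }
    parts <- c(parts, paste0("[", paste(toks[sp$start[k]:sp$end[k]],
                                        collapse = " "),
                             "|", sp$label[k], "]"))
    pos <- sp$end[k] + 1L
  }
  if (pos <= length(toks)) parts <- c(parts, toks[pos:length(toks)])
  paste(parts, collapse = " ")
}
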