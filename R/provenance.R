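# Bi-gram coverage provenance: is a summary segment reconstructible from
# the patient's own inpatient records?
#
# First step of the two-step origin classification: a bi-gram set is built
# from all inpatient records of the case, each discharge-summary segment is
# scored by the fraction of its word bi-gram occurrences found in that set,
# and segments at or above the threshold (default 0.5) are accepted as
# sourced. Below-threshold segments are only *suspected* unsourced; the
# second step (manual annotation in the original study, gold labels here)
# fixes their final origin. Symbolic segments and segments of middle
# subjectivity are excluded throughout.

#' Provenance configuration
#'
#' @param threshold Coverage at or above which a segment is sourced
#'   (default 0.5).
#' @param n_bins Number of equal-width bins partitioning `[0, threshold)`
#'   for the below-threshold analysis (default 5).
#' @param short_segment_policy What to do with segments of fewer than two
#'   tokens (no bi-gram exists): `"excluded"` (default) or `"unsourced"`.
#' @param count_mode `"occurrences"` (default; duplicated bi-grams counted
#'   each time they occur) or `"types"` (unique bi-grams).
#' @param cross_sentences If `TRUE`, record bi-grams may span sentence
#'   boundaries; default `FALSE`.
#' @return A list of class `ds_prov_config`.
#' @export
provenance_config <- function(threshold = 0.5, n_bins = 5L,
                              short_segment_policy = c("excluded", "unsourced"),
                              count_mode = c("occurrences", "types"),
                              cross_sentences = FALSE) {
  stopifnot(threshold > 0, threshold <= 1, n_bins >= 1L)
  structure(list(threshold = threshold, n_bins = as.integer(n_bins),
                 short_segment_policy = match.arg(short_segment_policy),
                 count_mode = match.arg(count_mode),
                 cross_sentences = isTRUE(cross_sentences)),
            class = "ds_prov_config")
}

bigram_keys <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(character(0))
  paste(tokens[-n], tokens[-1], sep = "\r")
}

#' Build the bi-gram set of a case's inpatient records
#'
#' Union over all inpatient-record documents of adjacent word-token pairs.
#' Pairs never span sentence boundaries unless configured otherwise;
#' direction matters.
#'
#' @param case A `ds_case` with at least one inpatient record.
#' @param tokenizer A tokenizer function; default [default_tokenizer()].
#' @param cfg A [provenance_config()].
#' @param seg_cfg A [seg_config()] supplying sentence delimiters.
#' @return A `ds_bigram_set`: list with `case_id`, `bigrams` (character
#'   set of `"tok1\\rtok2"` keys) and `source_doc_count`.
#' @export
build_bigram_set <- function(case, tokenizer = default_tokenizer(),
                             cfg = provenance_config(),
                             seg_cfg = seg_config()) {
  if (!length(case$inpatient_records)) stop("case has no inpatient records")
  keys <- character(0)
  for (rec in case$inpatient_records) {
    if (cfg$cross_sentences) {
      keys <- c(keys, bigram_keys(tokenizer(rec$text)))
    } else {
      sp <- split_sentences(rec$text, seg_cfg$delimiters)
      for (i in seq_len(nrow(sp))) {
        keys <- c(keys, bigram_keys(tokenizer(span_text(rec$text, sp[i, 1], sp[i, 2]))))
      }
    }
  }
  structure(list(case_id = case$case_id, bigrams = unique(keys),
                 source_doc_count = length(case$inpatient_records)),
            class = "ds_bigram_set")
}

#' Bi-gram coverage of a summary segment
#'
#' Fraction of the segment's bi-gram occurrences found in the record
#' bi-gram set. `NA` when the segment has fewer than two tokens.
#'
#' @param segment A `ds_segment` (or any object with a `text` field) of
#'   kind `discharge_summary`, or a character scalar.
#' @param bigrams A `ds_bigram_set` from [build_bigram_set()].
#' @param tokenizer A tokenizer function.
#' @param count_mode See [provenance_config()].
#' @return Real in `[0, 1]`, or `NA_real_`.
#' @export
coverage_ratio <- function(segment, bigrams, tokenizer = default_tokenizer(),
                           count_mode = "occurrences") {
  text <- if (is.character(segment)) segment else segment$text
  keys <- bigram_keys(tokenizer(text))
  if (count_mode == "types") keys <- unique(keys)
  if (!length(keys)) return(NA_real_)
  mean(keys %in% bigrams$bigrams)
}

#' Classify the origin of one summary segment
#'
#' A segment is `excluded` when symbolic, of (effective) middle
#' subjectivity, or too short to form a bi-gram under the default policy.
#' Otherwise it is `sourced` when coverage reaches the threshold, else
#' `unsourced` with a bin index `floor(coverage * n_bins / threshold)`
#' (clamped to `n_bins - 1`).
#'
#' @param coverage Real or `NA` from [coverage_ratio()].
#' @param segment The segment (for `is_symbolic` and gold labels).
#' @param cfg A [provenance_config()].
#' @param subjectivity Optional effective subjectivity tier to use (e.g. a
#'   model prediction); defaults to the segment's gold labels with the
#'   probable override applied.
#' @return List with `segment_id`, `coverage`, `origin`, `bin_index`.
#' @export
classify_origin <- function(coverage, segment, cfg = provenance_config(),
                            subjectivity = NULL) {
  if (is.null(subjectivity) && !is.null(segment$gold_labels)) {
    gl <- segment$gold_labels
    subjectivity <- effective_subjectivity(gl$subjectivity, gl$probable)
  }
  res <- list(segment_id = segment$segment_id, coverage = coverage,
              origin = "excluded", bin_index = NA_integer_)
  if (isTRUE(segment$is_symbolic)) return(res)
  if (identical(subjectivity, "middle")) return(res)
  if (is.na(coverage)) {
    if (cfg$short_segment_policy == "excluded") return(res)
    coverage <- 0
  }
  if (coverage >= cfg$threshold) {
    res$origin <- "sourced"
  } else {
    res$origin <- "unsourced"
    res$bin_index <- min(as.integer(floor(coverage * cfg$n_bins / cfg$threshold)),
                         cfg$n_bins - 1L)
  }
  res
}

#' Run provenance classification over a corpus
#'
#' @param cases List of `ds_case` objects.
#' @param cfg A [provenance_config()].
#' @param tokenizer A tokenizer function.
#' @param labels Optional data frame of predicted labels with columns
#'   `segment_id`, `subjectivity`, `probable`; when absent, gold labels on
#'   the segments are used.
#' @param seg_cfg A [seg_config()].
#' @return Data frame with columns `segment_id`, `case_id`, `coverage`,
#'   `origin` (machine origin: sourced/unsourced/excluded), `bin_index`.
#' @export
classify_corpus <- function(cases, cfg = provenance_config(),
                            tokenizer = default_tokenizer(), labels = NULL,
                            seg_cfg = seg_config()) {
  if (!is.null(labels)) {
    eff <- effective_subjectivity(labels$subjectivity, labels$probable)
    names(eff) <- labels$segment_id
  }
  rows <- list()
  for (case in cases) {
    bg <- build_bigram_set(case, tokenizer, cfg, seg_cfg)
    for (seg in case$segments) {
      if (seg$doc_kind != "discharge_summary") next
      cov <- coverage_ratio(seg, bg, tokenizer, cfg$count_mode)
      subj <- if (!is.null(labels)) unname(eff[seg$segment_id]) else NULL
      r <- classify_origin(cov, seg, cfg, subjectivity = subj)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = r$segment_id, case_id = case$case_id,
        coverage = r$coverage, origin = r$origin, bin_index = r$bin_index,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(segment_id = character(0), case_id = character(0),
                      coverage = numeric(0), origin = character(0),
                      bin_index = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

gold_origin_map <- function(cases) {
  out <- character(0)
  for (case in cases) {
    for (seg in case$segments) {
      if (!is.null(seg$gold_origin)) out[seg$segment_id] <- seg$gold_origin
    }
  }
  out
}

#' Resolve final origins (machine + second-step labels)
#'
#' Segments at or above the coverage threshold keep their machine origin
#' (`sourced`). Below-threshold segments take the second-step gold origin
#' when available (the analogue of the study's manual annotation, able to
#' rescue paraphrased-but-sourced segments); otherwise they stay
#' `unsourced`. Excluded segments stay excluded.
#'
#' @param results Data frame from [classify_corpus()].
#' @param cases The corpus (supplies gold origins), or a named character
#'   vector `segment_id -> origin`.
#' @return `results` with an additional `origin_final` column.
#' @export
resolve_origins <- function(results, cases) {
  gold <- if (is.character(cases)) cases else gold_origin_map(cases)
  fin <- results$origin
  below <- results$origin == "unsourced"
  hit <- below & results$segment_id %in% names(gold)
  fin[hit] <- unname(gold[results$segment_id[hit]])
  results$origin_final <- fin
  results
}

#' Segment-level unsourced rate
#'
#' Fraction of non-excluded summary segments whose final origin is
#' unsourced.
#'
#' @param results Data frame with an `origin_final` column
#'   (see [resolve_origins()]).
#' @return Real in `[0, 1]` (`NaN` when nothing is classified).
#' @export
segment_unsourced_rate <- function(results) {
  kept <- results$origin_final[results$origin_final != "excluded"]
  mean(kept == "unsourced")
}

#' Document-based unsourced rate
#'
#' Fraction of discharge summaries containing at least one unsourced,
#' non-excluded segment.
#'
#' @param cases List of `ds_case` objects.
#' @param results Data frame with `case_id` and `origin_final`.
#' @return Real in `[0, 1]`.
#' @export
document_unsourced_rate <- function(cases, results) {
  ids <- vapply(cases, function(c) c$case_id, character(1))
  with_uns <- unique(results$case_id[results$origin_final == "unsourced"])
  mean(ids %in% with_uns)
}

#' Unsourced proportion per coverage bin
#'
#' For the below-threshold segments, the machine can only suspect that a
#' segment is unsourced; this measures, per coverage bin, the fraction
#' whose (second-step) gold origin really is unsourced — the empirical
#' justification of the threshold.
#'
#' @param results Data frame from [classify_corpus()] (machine origins).
#' @param gold Named character vector `segment_id -> "sourced"/"unsourced"`,
#'   or a corpus (list of cases) from which gold origins are taken.
#' @param cfg A [provenance_config()].
#' @return Data frame with columns `bin_index` (0-based), `proportion_unsourced`
#'   (`NA` for empty bins) and `n`.
#' @export
bin_unsourced_proportions <- function(results, gold, cfg = provenance_config()) {
  if (!is.character(gold)) gold <- gold_origin_map(gold)
  below <- results[results$origin == "unsourced", , drop = FALSE]
  missing <- setdiff(below$segment_id, names(gold))
  if (length(missing)) {
    stop("missing gold origin for below-threshold segment(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  g <- unname(gold[below$segment_id])
  out <- data.frame(bin_index = seq_len(cfg$n_bins) - 1L,
                    proportion_unsourced = NA_real_, n = 0L)
  for (k in out$bin_index) {
    sel <- below$bin_index == k
    out$n[k + 1L] <- sum(sel)
    if (any(sel)) out$proportion_unsourced[k + 1L] <- mean(g[sel] == "unsourced")
  }
  out
}
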