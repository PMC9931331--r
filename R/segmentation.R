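# Preprocessing: sentence split, clinical-segment split, symbol flagging.
#
# Sentence splitting is deliberately primitive (end marks and line breaks):
# clinical text is noisy and a complex splitter would bias downstream
# statistics. The finer clinical-segment split is performed by a pluggable
# segmenter; the default is rule-based (commas, Japanese connective
# punctuation, a connective lexicon) standing in for an external ML model
# behind the same interface.

#' Segmentation configuration
#'
#' @param delimiters Characters ending a sentence. Default: Japanese and
#'   ASCII end marks plus line breaks.
#' @param connectives Strings at which the default segmenter opens a new
#'   clinical segment (boundary *before* the connective).
#' @param symbol_patterns Perl regexes; a segment matching any of them is
#'   flagged symbolic. Extend rather than replace for local conventions.
#' @return A list of class `ds_seg_config`.
#' @export
seg_config <- function(delimiters = c("。", ".", "!", "?", "\n"),
                       connectives = c("しかし",
                                       "そのため",
                                       "ただし"),
                       symbol_patterns = c(
                         "^\\s*【[^】]*】\\s*$",
                         "^\\s*\\d{1,4}[/.年-]\\s*\\d{1,2}[/.月-]\\s*\\d{1,2}日?(\\s+\\d{1,2}:\\d{2})?\\s*$",
                         "^[^\\p{L}]*$")) {
  structure(list(delimiters = delimiters, connectives = connectives,
                 symbol_patterns = symbol_patterns),
            class = "ds_seg_config")
}

#' Split text into sentence spans
#'
#' A linear scan over characters: any delimiter character closes the
#' current sentence. Delimiter characters themselves are not part of any
#' span and empty spans are dropped.
#'
#' @param text Character scalar (may be empty).
#' @param delimiters Character vector of single-character delimiters.
#' @return Integer matrix with columns `start`, `end` (0-based half-open),
#'   one row per sentence.
#' @export
#' @examples
#' split_sentences("ab. cd.")
split_sentences <- function(text, delimiters = seg_config()$delimiters) {
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (is.null(text) || !nzchar(text)) return(empty)
  ch <- strsplit(text, "", fixed = FALSE)[[1]]
  is_delim <- ch %in% delimiters
  if (all(is_delim)) return(empty)
  r <- rle(!is_delim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  m <- cbind(start = starts[keep], end = ends[keep])
  m[m[, "end"] > m[, "start"], , drop = FALSE]
}

#' Rule-based clinical segmenter
#'
#' Returns a segmenter function (the default implementation of the
#' segmenter contract): it cuts a sentence after every comma-like
#' character run and before every occurrence of a connective from the
#' lexicon, returning the ordered pieces whose concatenation reproduces
#' the sentence exactly.
#'
#' @param connectives Connective lexicon (see [seg_config()]).
#' @return `function(sentence) -> character vector` of pieces.
#' @export
default_segmenter <- function(connectives = seg_config()$connectives) {
  force(connectives)
  function(sentence) {
    n <- nchar(sentence)
    if (n == 0L) return(character(0))
    cuts <- integer(0)
    # boundary after each comma run
    m <- gregexpr("[,、，;；]+", sentence, perl = TRUE)[[1]]
    if (m[1] != -1L) cuts <- c(cuts, as.integer(m) + attr(m, "match.length") - 1L)
    # boundary before each connective occurrence
    for (cn in connectives) {
      mm <- gregexpr(cn, sentence, fixed = TRUE)[[1]]
      if (mm[1] != -1L) cuts <- c(cuts, as.integer(mm) - 1L)
    }
    cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
    bounds <- c(0L, cuts, n)
    substring(sentence, bounds[-length(bounds)] + 1L, bounds[-1])
  }
}

#' Split a sentence into clinical segment spans
#'
#' Applies a segmenter satisfying the contract (ordered pieces that
#' concatenate back to the sentence) and converts the pieces to 0-based
#' half-open spans within the sentence. A segmenter whose output is not a
#' partition of the sentence is rejected.
#'
#' @param sentence Character scalar.
#' @param segmenter A segmenter function; default [default_segmenter()].
#' @return Integer matrix with columns `start`, `end`.
#' @export
split_clinical_segments <- function(sentence, segmenter = default_segmenter()) {
  if (!nzchar(sentence)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  pieces <- segmenter(sentence)
  if (!identical(paste(pieces, collapse = ""), sentence)) {
    stop("segmenter contract violation: pieces do not reconstruct the sentence")
  }
  ends <- cumsum(nchar(pieces))
  starts <- ends - nchar(pieces)
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Flag symbolic segments
#'
#' Symbolic segments (dates, bracketed headers, system symbols, anything
#' without a letter character) carry no patient information and are
#' excluded from provenance classification.
#'
#' @param text Character vector of segment texts.
#' @param patterns Perl regexes; see [seg_config()].
#' @return Logical vector.
#' @export
#' @examples
#' flag_symbolic(c("2020/04/10", "Discharged."))
flag_symbolic <- function(text, patterns = seg_config()$symbol_patterns) {
  out <- rep(FALSE, length(text))
  for (p in patterns) out <- out | grepl(p, text, perl = TRUE)
  out
}

#' Segment one document into clinical segments
#'
#' Runs the sentence splitter then the clinical segmenter and returns
#' segments with spans rebased to the whole document.
#'
#' @param text Document text.
#' @param case_id,doc_kind,doc_index Identity of the parent document.
#' @param section Section tag applied to every produced segment.
#' @param config A [seg_config()].
#' @param segmenter Optional segmenter overriding the config default.
#' @return List of `ds_segment` objects (no gold labels).
#' @export
segment_document <- function(text, case_id, doc_kind, doc_index = 1L,
                             section = "unknown", config = seg_config(),
                             segmenter = default_segmenter(config$connectives)) {
  sents <- split_sentences(text, config$delimiters)
  segs <- list()
  k <- 0L
  for (i in seq_len(nrow(sents))) {
    s0 <- sents[i, "start"]
    sent <- span_text(text, s0, sents[i, "end"])
    spans <- split_clinical_segments(sent, segmenter)
    for (j in seq_len(nrow(spans))) {
      k <- k + 1L
      st <- s0 + spans[j, "start"]; en <- s0 + spans[j, "end"]
      seg_text <- span_text(text, st, en)
      segs[[k]] <- new_segment(
        segment_id = sprintf("%s-%s%d-%03d", case_id,
                             if (doc_kind == "discharge_summary") "s" else "r",
                             doc_index, k),
        case_id = case_id, doc_kind = doc_kind, doc_index = doc_index,
        char_span = c(st, en), text = seg_text, section = section,
        is_symbolic = flag_symbolic(seg_text, config$symbol_patterns))
    }
  }
  segs
}

#' Re-segment every document of a case
#'
#' Replaces `case$segments` with segments derived from the raw documents.
#' Any gold labels present on prior segments are dropped; use this on raw
#' (unlabeled) corpora or when auditing new text.
#'
#' @param case A `ds_case`.
#' @param config A [seg_config()].
#' @return The case with refreshed segments.
#' @export
segment_case <- function(case, config = seg_config()) {
  segs <- list()
  for (i in seq_along(case$inpatient_records)) {
    segs <- c(segs, segment_document(case$inpatient_records[[i]]$text,
                                     case$case_id, "inpatient_record", i,
                                     config = config))
  }
  segs <- c(segs, segment_document(case$discharge_summary$text, case$case_id,
                                   "discharge_summary", 1L, config = config))
  case$segments <- segs
  validate_case(case)
  case
}
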