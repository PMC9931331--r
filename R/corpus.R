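# Corpus domain objects and the JSON Lines interchange format.
#
# A corpus is a list of cases; a case pairs the inpatient records of one
# admission with its discharge summary, plus the clinical segments cut from
# those documents. One case is serialized per line as a UTF-8 JSON object
# with a fixed key order, so that serialization is byte-deterministic and
# write -> read -> write is a fixpoint.

.DOC_KINDS <- c("inpatient_record", "discharge_summary")
.SECTIONS <- c("pre_hospital", "in_hospital", "unknown")
.ORIGINS <- c("sourced", "unsourced")

#' Construct a clinical segment
#'
#' The atomic unit of the audit: a contiguous span of one parent document.
#' Offsets are 0-based half-open character offsets into the parent document
#' (`doc_index`-th inpatient record, or the discharge summary).
#'
#' @param segment_id,case_id Opaque identifiers.
#' @param doc_kind `"inpatient_record"` or `"discharge_summary"`.
#' @param doc_index 1-based index of the parent inpatient record (1 for the
#'   discharge summary).
#' @param char_span Integer vector `c(start, end)`, 0-based half-open.
#' @param text The segment text; must equal the parent substring.
#' @param section `"pre_hospital"`, `"in_hospital"` or `"unknown"`.
#' @param is_symbolic Logical: dates, symbols, system output.
#' @param gold_labels Optional [label_set()].
#' @param gold_origin Optional `"sourced"`/`"unsourced"` (summaries only).
#' @param gold_sources Optional character vector of [source_doc_labels()];
#'   required non-empty exactly when `gold_origin == "unsourced"`.
#' @param extras Named list of unknown fields carried through round-trips.
#' @return A `ds_segment` object.
#' @export
new_segment <- function(segment_id, case_id, doc_kind, doc_index, char_span,
                        text, section = "unknown", is_symbolic = FALSE,
                        gold_labels = NULL, gold_origin = NULL,
                        gold_sources = NULL, extras = list()) {
  structure(
    list(segment_id = as.character(segment_id),
         case_id = as.character(case_id),
         doc_kind = doc_kind,
         doc_index = as.integer(doc_index),
         char_span = as.integer(char_span),
         text = text,
         section = section,
         is_symbolic = isTRUE(is_symbolic),
         gold_labels = gold_labels,
         gold_origin = gold_origin,
         gold_sources = gold_sources,
         extras = extras),
    class = "ds_segment"
  )
}

#' Construct a case
#'
#' @param case_id,hospital_id Opaque identifiers.
#' @param inpatient_records List of documents, each `list(date =, text =)`.
#' @param discharge_summary One document, `list(date =, text =)`.
#' @param segments List of [new_segment()] objects.
#' @param extras Named list of unknown fields carried through round-trips.
#' @return A `ds_case` object.
#' @export
new_case <- function(case_id, hospital_id, inpatient_records,
                     discharge_summary, segments = list(), extras = list()) {
  structure(
    list(case_id = as.character(case_id),
         hospital_id = as.character(hospital_id),
         inpatient_records = inpatient_records,
         discharge_summary = discharge_summary,
         segments = segments,
         extras = extras),
    class = "ds_case"
  )
}

#' @export
print.ds_case <- function(x, ...) {
  cat(sprintf("<ds_case %s> hospital %s: %d inpatient record(s), %d segment(s)\n",
              x$case_id, x$hospital_id, length(x$inpatient_records),
              length(x$segments)))
  invisible(x)
}

fail_case <- function(case_id, field, msg) {
  stop(sprintf("invalid case '%s' (field '%s'): %s", case_id, field, msg),
       call. = FALSE)
}

#' Validate a case against the corpus schema
#'
#' Checks structural invariants: at least one inpatient record and exactly
#' one discharge summary; segment spans are 0-based half-open with
#' `end > start` and `text` equal to the parent document substring;
#' `gold_origin`/`gold_sources` appear only on discharge-summary segments;
#' `gold_sources` is non-empty exactly when `gold_origin == "unsourced"`.
#'
#' @param case A `ds_case`.
#' @return The case, invisibly. Errors name the case id and failing field.
#' @export
validate_case <- function(case) {
  cid <- case$case_id
  if (!length(case$inpatient_records)) {
    fail_case(cid, "inpatient_records", "at least one inpatient record required")
  }
  for (rec in case$inpatient_records) {
    if (!is.character(rec$text %||% NULL)) {
      fail_case(cid, "inpatient_records", "each record needs a character 'text'")
    }
  }
  if (!is.character(case$discharge_summary$text %||% NULL)) {
    fail_case(cid, "discharge_summary", "exactly one summary with character 'text' required")
  }
  for (seg in case$segments) {
    sid <- seg$segment_id
    if (!seg$doc_kind %in% .DOC_KINDS) {
      fail_case(cid, "doc_kind", sprintf("segment %s: unknown kind '%s'", sid, seg$doc_kind))
    }
    if (!seg$section %in% .SECTIONS) {
      fail_case(cid, "section", sprintf("segment %s: unknown section '%s'", sid, seg$section))
    }
    sp <- seg$char_span
    if (length(sp) != 2L || is.na(sp[1]) || is.na(sp[2]) || sp[2] <= sp[1] || sp[1] < 0) {
      fail_case(cid, "char_span", sprintf("segment %s: need 0 <= start < end", sid))
    }
    parent <- if (seg$doc_kind == "discharge_summary") {
      case$discharge_summary$text
    } else {
      if (seg$doc_index < 1L || seg$doc_index > length(case$inpatient_records)) {
        fail_case(cid, "doc_index", sprintf("segment %s: doc_index out of range", sid))
      }
      case$inpatient_records[[seg$doc_index]]$text
    }
    if (!identical(span_text(parent, sp[1], sp[2]), seg$text)) {
      fail_case(cid, "text", sprintf("segment %s: text does not match parent substring", sid))
    }
    if (seg$doc_kind != "discharge_summary" &&
        (!is.null(seg$gold_origin) || !is.null(seg$gold_sources))) {
      fail_case(cid, "gold_origin",
                sprintf("segment %s: provenance gold labels only on summary segments", sid))
    }
    if (!is.null(seg$gold_origin) && !seg$gold_origin %in% .ORIGINS) {
      fail_case(cid, "gold_origin", sprintf("segment %s: unknown origin '%s'", sid, seg$gold_origin))
    }
    has_src <- length(seg$gold_sources) > 0L
    is_unsourced <- identical(seg$gold_origin, "unsourced")
    if (has_src != is_unsourced) {
      fail_case(cid, "gold_sources",
                sprintf("segment %s: gold_sources must be non-empty iff gold_origin is 'unsourced'", sid))
    }
    if (has_src) {
      bad <- setdiff(seg$gold_sources, source_doc_labels())
      if (length(bad)) {
        fail_case(cid, "gold_sources", sprintf("segment %s: unknown label(s) %s",
                                               sid, paste(bad, collapse = ", ")))
      }
    }
    gl <- seg$gold_labels
    if (!is.null(gl)) {
      if (!gl$role %in% clinical_roles()) {
        fail_case(cid, "gold_labels", sprintf("segment %s: unknown role '%s'", sid, gl$role))
      }
      if (!gl$subjectivity %in% subjectivity_tiers()) {
        fail_case(cid, "gold_labels", sprintf("segment %s: unknown tier '%s'", sid, gl$subjectivity))
      }
      if (!is.logical(gl$probable) || is.na(gl$probable)) {
        fail_case(cid, "gold_labels", sprintf("segment %s: probable must be TRUE/FALSE", sid))
      }
    }
  }
  invisible(case)
}

doc_to_json <- function(doc) {
  out <- list()
  if (!is.null(doc$date)) out$date <- doc$date
  out$text <- doc$text
  out
}

seg_to_json <- function(seg) {
  out <- list(segment_id = seg$segment_id,
              case_id = seg$case_id,
              doc_kind = seg$doc_kind,
              doc_index = seg$doc_index,
              char_span = seg$char_span,
              text = seg$text,
              section = seg$section,
              is_symbolic = seg$is_symbolic)
  if (!is.null(seg$gold_labels)) {
    gl <- seg$gold_labels
    out$gold_labels <- list(subjectivity = gl$subjectivity, role = gl$role,
                            probable = gl$probable)
  }
  if (!is.null(seg$gold_origin)) out$gold_origin <- seg$gold_origin
  if (length(seg$gold_sources)) out$gold_sources <- I(as.character(seg$gold_sources))
  if (length(seg$extras)) out$extras <- seg$extras
  out
}

case_to_json <- function(case) {
  out <- list(case_id = case$case_id,
              hospital_id = case$hospital_id,
              inpatient_records = lapply(case$inpatient_records, doc_to_json),
              discharge_summary = doc_to_json(case$discharge_summary),
              segments = lapply(case$segments, seg_to_json))
  if (length(case$extras)) out$extras <- case$extras
  out
}

known_seg_fields <- c("segment_id", "case_id", "doc_kind", "doc_index",
                      "char_span", "text", "section", "is_symbolic",
                      "gold_labels", "gold_origin", "gold_sources", "extras")

seg_from_json <- function(x) {
  gl <- x$gold_labels
  if (!is.null(gl)) {
    gl <- list(subjectivity = gl$subjectivity, role = gl$role,
               probable = isTRUE(gl$probable))
  }
  extras <- x$extras %||% list()
  unknown <- x[setdiff(names(x), known_seg_fields)]
  if (length(unknown)) extras <- c(extras, unknown)
  new_segment(segment_id = x$segment_id, case_id = x$case_id,
              doc_kind = x$doc_kind, doc_index = x$doc_index %||% 1L,
              char_span = unlist(x$char_span), text = x$text,
              section = x$section %||% "unknown",
              is_symbolic = isTRUE(x$is_symbolic),
              gold_labels = gl,
              gold_origin = x$gold_origin,
              gold_sources = if (length(x$gold_sources)) unlist(x$gold_sources),
              extras = extras)
}

known_case_fields <- c("case_id", "hospital_id", "inpatient_records",
                       "discharge_summary", "segments", "extras")

case_from_json <- function(x) {
  extras <- x$extras %||% list()
  unknown <- x[setdiff(names(x), known_case_fields)]
  if (length(unknown)) extras <- c(extras, unknown)
  new_case(case_id = x$case_id,
           hospital_id = x$hospital_id %||% "unknown",
           inpatient_records = lapply(x$inpatient_records, function(d) {
             list(date = d$date, text = d$text)
           }),
           discharge_summary = list(date = x$discharge_summary$date,
                                    text = x$discharge_summary$text),
           segments = lapply(x$segments, seg_from_json),
           extras = extras)
}

#' Read a corpus from JSON Lines
#'
#' One case per line; unknown fields are preserved in each object's
#' `extras` map and survive [write_corpus()].
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return List of validated `ds_case` objects, in file order.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  cases <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed JSON on line %d: %s", i, conditionMessage(e)),
                         call. = FALSE)
                  })
    cases[[i]] <- validate_case(case_from_json(x))
  }
  cases
}

#' Write a corpus as canonical JSON Lines
#'
#' Keys are emitted in a fixed, documented order and optional fields are
#' omitted when absent, so equal inputs always produce identical bytes.
#'
#' @param cases List of `ds_case` objects (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(cases, path) {
  lines <- vapply(cases, function(case) {
    validate_case(case)
    as.character(jsonlite::toJSON(case_to_json(case), auto_unbox = TRUE,
                                  digits = NA, null = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
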