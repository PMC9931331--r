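# Fixtures are built in code; no files are stored.

# A hand-built two-record case with one summary segment copied verbatim
# from a record and one alien segment.
tiny_case <- function(case_id = "t001") {
  rec1 <- "alpha beta gamma。delta beta"
  rec2 <- "epsilon zeta"
  summ <- "alpha beta gamma。omega psi chi"
  segs <- list(
    new_segment("t001-s1", case_id, "discharge_summary", 1L, c(0L, 16L),
                "alpha beta gamma", section = "pre_hospital",
                gold_labels = label_set("description"),
                gold_origin = "sourced"),
    new_segment("t001-s2", case_id, "discharge_summary", 1L, c(17L, 30L),
                "omega psi chi", section = "in_hospital",
                gold_labels = label_set("diag"),
                gold_origin = "unsourced",
                gold_sources = "past_clinical_records")
  )
  new_case(case_id, "H1",
           list(list(date = "2020-04-01", text = rec1),
                list(date = "2020-04-02", text = rec2)),
           list(date = "2020-04-03", text = summ),
           segs)
}

# Independent nested-loop bi-gram oracle over token lists (one list per
# record sentence). Counts segment bi-gram occurrences found anywhere.
oracle_coverage <- function(seg_tokens, record_sentences) {
  n <- length(seg_tokens)
  if (n < 2) return(NA_real_)
  found <- 0L
  for (i in seq_len(n - 1)) {
    hit <- FALSE
    for (sent in record_sentences) {
      m <- length(sent)
      if (m < 2) next
      for (j in seq_len(m - 1)) {
        if (sent[j] == seg_tokens[i] && sent[j + 1] == seg_tokens[i + 1]) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (hit) found <- found + 1L
  }
  found / (n - 1)
}

# Build a ds_case from token lists (records: list of list of sentences,
# each a token vector; summary_sentences likewise). Segments get trivial
# gold labels unless supplied.
case_from_tokens <- function(records, summary_sentences, case_id = "tok1",
                             roles = NULL) {
  rec_docs <- lapply(seq_along(records), function(d) {
    list(date = sprintf("2020-04-%02d", d),
         text = paste(vapply(records[[d]], paste, character(1), collapse = " "),
                      collapse = "。"))
  })
  texts <- vapply(summary_sentences, paste, character(1), collapse = " ")
  summ <- paste(texts, collapse = "。")
  ends <- cumsum(nchar(texts) + 1L) - 1L
  starts <- ends - nchar(texts)
  segs <- lapply(seq_along(texts), function(i) {
    new_segment(sprintf("%s-s1-%03d", case_id, i), case_id,
                "discharge_summary", 1L, c(starts[i], ends[i]), texts[i],
                gold_labels = label_set(if (is.null(roles)) "description" else roles[i]))
  })
  new_case(case_id, "H1", rec_docs, list(date = "2020-04-30", text = summ),
           segs)
}

# A small labeled frame with marker tokens (cheap classifier fixture).
labeled_frame <- function(n, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    roles <- clinical_roles()
    marks <- c(description = "descmk", action = "actnmk", others = "othrmk",
               result = "rsltmk", undefinable = "undfmk",
               evaluation = "evalmk", diag = "diagmk", plan = "planmk",
               nonfact = "nfctmk")
    role <- sample(roles, n, replace = TRUE)
    probable <- runif(n) < 0.15
    text <- vapply(seq_len(n), function(i) {
      paste(c(marks[[role[i]]], if (probable[i]) "probmk",
              sample(paste0("tok", letters[1:20]), 5, replace = TRUE)),
            collapse = " ")
    }, character(1))
    data.frame(segment_id = sprintf("lf-%03d", seq_len(n)), text = text,
               subjectivity = effective_subjectivity(role_tier(role), probable),
               role = role, probable = probable, stringsAsFactors = FALSE)
  })
}

# A fixed 20-segment audit frame with hand-computable rates:
# hospital H1: 4 low description (1 unsourced), 4 high diag (2 unsourced)
# hospital H2: 4 low action (2 unsourced), 2 middle result (excluded),
#              2 symbolic (excluded), 4 high plan (3 unsourced, 1 probable)
fixture_frame <- function() {
  seg <- function(id, hosp, sec, role, probable, origin, symbolic = FALSE,
                  sources = NULL) {
    data.frame(segment_id = id, case_id = paste0("c", hosp),
               hospital_id = hosp, section = sec, is_symbolic = symbolic,
               subjectivity = effective_subjectivity(role_tier(role), probable),
               tier = effective_subjectivity(role_tier(role), probable),
               role = role, probable = probable, origin = origin,
               sources = I(list(sources)), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in 1:4) {
    rows <- c(rows, list(seg(paste0("a", i), "H1", "pre_hospital",
                             "description", FALSE,
                             if (i == 1) "unsourced" else "sourced",
                             sources = if (i == 1) "past_clinical_records")))
  }
  for (i in 1:4) {
    rows <- c(rows, list(seg(paste0("b", i), "H1", "in_hospital", "diag",
                             FALSE, if (i <= 2) "unsourced" else "sourced",
                             sources = if (i <= 2) "no_document")))
  }
  for (i in 1:4) {
    rows <- c(rows, list(seg(paste0("d", i), "H2", "pre_hospital", "action",
                             FALSE, if (i <= 2) "unsourced" else "sourced",
                             sources = if (i <= 2) c("patient_referral",
                                                     "prescriptions"))))
  }
  for (i in 1:2) {
    rows <- c(rows, list(seg(paste0("e", i), "H2", "in_hospital", "result",
                             FALSE, "excluded")))
  }
  for (i in 1:2) {
    rows <- c(rows, list(seg(paste0("f", i), "H2", "in_hospital", "others",
                             FALSE, "excluded", symbolic = TRUE)))
  }
  for (i in 1:4) {
    rows <- c(rows, list(seg(paste0("g", i), "H2", "in_hospital", "plan",
                             i == 1, if (i <= 3) "unsourced" else "sourced",
                             sources = if (i <= 3) "outpatient_records")))
  }
  do.call(rbind, rows)
}
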