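# Evaluation metrics and stratified unsourced-rate / attribution tables.

# Macro F1 over the classes present in gold (1-based integer codes).
macro_f1_int <- function(pred, gold, k) {
  f1 <- vapply(seq_len(k), function(c) {
    tp <- sum(pred == c & gold == c)
    fp <- sum(pred == c & gold != c)
    fn <- sum(pred != c & gold == c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  present <- vapply(seq_len(k), function(c) any(gold == c), logical(1))
  mean(f1[present])
}

task_report <- function(pred, gold, classes) {
  per <- lapply(seq_along(classes), function(c) {
    tp <- sum(pred == c & gold == c)
    fp <- sum(pred == c & gold != c)
    fn <- sum(pred != c & gold == c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = classes[c], tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  present <- per$class %in% classes[sort(unique(gold))]
  list(per_class = per, macro_f1 = mean(per$f1[present]),
       macro_precision = mean(per$precision[present]),
       macro_recall = mean(per$recall[present]))
}

#' Evaluate predicted label sets against gold
#'
#' Per-class and macro precision/recall/F1 for each of the three tasks.
#' Zero-denominator precision, recall and F1 are defined as 0; macro
#' averages run over the classes present in gold.
#'
#' @param pred,gold Aligned data frames with columns `subjectivity`,
#'   `role`, `probable`.
#' @return List with elements `sub`, `role`, `prob`, each holding
#'   `per_class` (data frame) and `macro_f1`/`macro_precision`/`macro_recall`.
#' @export
evaluate <- function(pred, gold) {
  if (nrow(pred) != nrow(gold)) stop("pred and gold must have the same length")
  list(
    sub = task_report(match(pred$subjectivity, subjectivity_tiers()),
                      match(gold$subjectivity, subjectivity_tiers()),
                      subjectivity_tiers()),
    role = task_report(match(pred$role, clinical_roles()),
                       match(gold$role, clinical_roles()),
                       clinical_roles()),
    prob = task_report(as.integer(pred$probable) + 1L,
                       as.integer(gold$probable) + 1L,
                       c("negative", "positive"))
  )
}

#' Assemble the per-segment audit frame
#'
#' One row per discharge-summary segment with everything the stratified
#' tables need: labels (gold by default, predictions when supplied — the
#' analogue of running the automatic labeler on unannotated data), the
#' effective subjectivity tier (probable implies high), final origin, and
#' case metadata.
#'
#' @param cases The corpus.
#' @param results Data frame with `segment_id` and `origin_final`
#'   (see [resolve_origins()]).
#' @param labels Optional predicted labels (`segment_id`, `subjectivity`,
#'   `role`, `probable`); gold labels are used when absent.
#' @return Data frame with columns `segment_id`, `case_id`, `hospital_id`,
#'   `section`, `is_symbolic`, `subjectivity` (raw tier), `tier`
#'   (effective), `role`, `probable`, `origin` and a list column `sources`.
#' @export
audit_frame <- function(cases, results, labels = NULL) {
  fin <- results$origin_final
  names(fin) <- results$segment_id
  if (!is.null(labels)) {
    lab <- labels
    rownames(lab) <- lab$segment_id
  }
  rows <- list()
  for (case in cases) {
    for (seg in case$segments) {
      if (seg$doc_kind != "discharge_summary") next
      if (!is.null(labels) && seg$segment_id %in% rownames(lab)) {
        l <- lab[seg$segment_id, ]
        subj <- l$subjectivity; role <- l$role; prob <- l$probable
      } else if (!is.null(seg$gold_labels)) {
        subj <- seg$gold_labels$subjectivity
        role <- seg$gold_labels$role
        prob <- seg$gold_labels$probable
      } else {
        subj <- NA_character_; role <- NA_character_; prob <- NA
      }
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = seg$segment_id, case_id = case$case_id,
        hospital_id = case$hospital_id, section = seg$section,
        is_symbolic = seg$is_symbolic, subjectivity = subj,
        tier = if (is.na(subj)) NA_character_ else effective_subjectivity(subj, isTRUE(prob)),
        role = role, probable = prob,
        origin = unname(fin[seg$segment_id]) %||% NA_character_,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$sources <- list(seg$gold_sources)
    }
  }
  do.call(rbind, rows)
}

rate_row <- function(stratum, kind, sel, frame) {
  n <- sum(sel)
  data.frame(stratum = stratum, kind = kind, n = n,
             rate = if (n > 0) mean(frame$origin[sel] == "unsourced") else NA_real_,
             stringsAsFactors = FALSE)
}

#' Unsourced rate by clinical role and subjectivity tier
#'
#' Excluded segments (symbolic, middle subjectivity, too short) never
#' enter any rate. Role rows and tier rows are computed independently of
#' each other; "all" is the rate over every non-excluded segment, i.e.
#' the weighted average of the low and high tiers only.
#'
#' @param frame An [audit_frame()].
#' @return Data frame with `stratum`, `kind` (`role`/`tier`/`probable`/`all`),
#'   `n`, `rate`.
#' @export
unsourced_by_label <- function(frame) {
  kept <- frame[!is.na(frame$origin) & frame$origin != "excluded" &
                  !frame$is_symbolic & !is.na(frame$tier) &
                  frame$tier != "middle", , drop = FALSE]
  out <- list()
  for (role in setdiff(clinical_roles(), c("result", "undefinable"))) {
    out[[length(out) + 1L]] <- rate_row(role, "role", kept$role == role, kept)
  }
  out[[length(out) + 1L]] <- rate_row("probable", "probable",
                                      kept$probable %in% TRUE, kept)
  for (tier in c("low", "high")) {
    out[[length(out) + 1L]] <- rate_row(tier, "tier", kept$tier == tier, kept)
  }
  out[[length(out) + 1L]] <- rate_row("all", "all", rep(TRUE, nrow(kept)), kept)
  do.call(rbind, out)
}

#' Unsourced and high-subjectivity rates by section
#'
#' The unsourced rate runs over non-excluded segments of the section; the
#' high-subjectivity rate over all non-symbolic labeled segments of the
#' section (middle stays in that denominator). Segments with section
#' `unknown` are omitted.
#'
#' @param frame An [audit_frame()].
#' @return Data frame with `stratum`, `n`, `rate`, `high_subj_rate`.
#' @export
unsourced_by_section <- function(frame) {
  out <- list()
  classifiable <- !is.na(frame$origin) & frame$origin != "excluded" &
    !frame$is_symbolic & !is.na(frame$tier) & frame$tier != "middle"
  for (sec in c("pre_hospital", "in_hospital")) {
    kept <- frame$section == sec & classifiable
    lab <- frame$section == sec & !frame$is_symbolic & !is.na(frame$tier)
    out[[length(out) + 1L]] <- data.frame(
      stratum = sec, n = sum(kept),
      rate = if (any(kept)) mean(frame$origin[kept] == "unsourced") else NA_real_,
      high_subj_rate = if (any(lab)) mean(frame$tier[lab] == "high") else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Unsourced and high-subjectivity rates by hospital
#'
#' @param frame An [audit_frame()].
#' @return Data frame with `stratum` (hospital id), `n`, `rate`,
#'   `high_subj_rate`. Hospitals without classifiable segments are
#'   omitted with a warning.
#' @export
unsourced_by_hospital <- function(frame) {
  out <- list()
  classifiable <- !is.na(frame$origin) & frame$origin != "excluded" &
    !frame$is_symbolic & !is.na(frame$tier) & frame$tier != "middle"
  for (h in unique(frame$hospital_id)) {
    kept <- frame$hospital_id == h & classifiable
    lab <- frame$hospital_id == h & !frame$is_symbolic & !is.na(frame$tier)
    if (!any(kept)) {
      warning("hospital ", h, " has no classifiable segments; omitted")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      stratum = h, n = sum(kept),
      rate = mean(frame$origin[kept] == "unsourced"),
      high_subj_rate = if (any(lab)) mean(frame$tier[lab] == "high") else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

pct_of_labels <- function(frames_sources) {
  counts <- table(factor(unlist(frames_sources), levels = source_doc_labels()))
  total <- sum(counts)
  if (total == 0) rep(NA_real_, length(source_doc_labels()))
  else as.numeric(counts) / total * 100
}

#' Attribution of unsourced segments to external sources
#'
#' Each unsourced segment carries one or more of the 14 source-document
#' labels; percentages are computed against the total number of assigned
#' labels (a segment with two labels contributes two to the denominator),
#' overall and stratified by effective tier and section.
#'
#' @param frame An [audit_frame()].
#' @return Data frame with `label`, `group`, `pct_all`, `pct_low`,
#'   `pct_high`, `pct_pre`, `pct_in`.
#' @export
attribution_breakdown <- function(frame) {
  uns <- frame[!is.na(frame$origin) & frame$origin == "unsourced" &
                 !frame$is_symbolic & !is.na(frame$tier) &
                 frame$tier != "middle", , drop = FALSE]
  empty <- vapply(uns$sources, function(s) length(s) == 0L, logical(1))
  if (any(empty)) {
    stop("unsourced segment(s) without source labels: ",
         paste(utils::head(uns$segment_id[empty], 5), collapse = ", "))
  }
  data.frame(
    label = source_doc_labels(),
    group = source_doc_group(source_doc_labels()),
    pct_all = pct_of_labels(uns$sources),
    pct_low = pct_of_labels(uns$sources[uns$tier == "low"]),
    pct_high = pct_of_labels(uns$sources[uns$tier == "high"]),
    pct_pre = pct_of_labels(uns$sources[uns$section == "pre_hospital"]),
    pct_in = pct_of_labels(uns$sources[uns$section == "in_hospital"]),
    stringsAsFactors = FALSE)
}

#' Overall information-source breakdown
#'
#' Combines the segment-level sourced rate with the attribution mixture:
#' the inpatient-record share is the sourced rate and each external
#' source's share is `(1 - sourced_rate)` times its attribution share.
#' Shares sum to 1.
#'
#' @param sourced_rate Real in `[0, 1]`.
#' @param attribution Data frame from [attribution_breakdown()].
#' @return Data frame with `source` and `share`, largest first
#'   (inpatient records always the first row).
#' @export
overall_breakdown <- function(sourced_rate, attribution) {
  stopifnot(sourced_rate >= 0, sourced_rate <= 1)
  if (sourced_rate >= 1 || all(is.na(attribution$pct_all))) {
    return(data.frame(source = "inpatient_records", share = sourced_rate,
                      stringsAsFactors = FALSE))
  }
  ext <- data.frame(source = attribution$label,
                    share = (1 - sourced_rate) * attribution$pct_all / 100,
                    stringsAsFactors = FALSE)
  ext <- ext[order(-ext$share), ]
  rbind(data.frame(source = "inpatient_records", share = sourced_rate,
                   stringsAsFactors = FALSE),
        ext)
}

#' Write the report tables as CSV
#'
#' Emits `t5_labels.csv`, `t6_sections.csv`, `t7_attribution.csv`,
#' `t8_hospitals.csv` and `fig6_breakdown.csv` into `dir`.
#'
#' @param frame An [audit_frame()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_reports <- function(frame, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t5 <- unsourced_by_label(frame)
  t6 <- unsourced_by_section(frame)
  t7 <- attribution_breakdown(frame)
  t8 <- unsourced_by_hospital(frame)
  sourced_rate <- 1 - t5$rate[t5$kind == "all"]
  fig6 <- overall_breakdown(sourced_rate, t7)
  files <- c(t5_labels = "t5_labels.csv", t6_sections = "t6_sections.csv",
             t7_attribution = "t7_attribution.csv",
             t8_hospitals = "t8_hospitals.csv",
             fig6_breakdown = "fig6_breakdown.csv")
  tabs <- list(t5, t6, t7, t8, fig6)
  paths <- file.path(dir, files)
  for (i in seq_along(tabs)) {
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE)
  }
  invisible(paths)
}
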