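# Label taxonomy: clinical roles, subjectivity tiers, source-document labels.

#' Clinical role labels
#'
#' The nine clinical-role labels assigned to a clinical segment. Each role
#' belongs to exactly one subjectivity tier (see [role_tier()]). The
#' `probable` flag is deliberately *not* a tenth role: it is a separate
#' binary task that can be attached to any role and promotes the segment to
#' high subjectivity for aggregation (see [effective_subjectivity()]).
#'
#' @return Character vector of the nine role names.
#' @export
#' @examples
#' clinical_roles()
clinical_roles <- function() {
  c("description", "action", "others",
    "result", "undefinable",
    "evaluation", "diag", "plan", "nonfact")
}

#' Subjectivity tiers
#'
#' Three-level gradation of subjectivity: `low` (facts and past actions),
#' `middle` (borderline or linguistically ambiguous content, excluded from
#' provenance aggregation), `high` (reasoning, diagnoses, plans, hearsay).
#'
#' @return Character vector `c("low", "middle", "high")`.
#' @export
subjectivity_tiers <- function() c("low", "middle", "high")

.ROLE_TIER <- c(
  description = "low",  action = "low",      others = "low",
  result = "middle",    undefinable = "middle",
  evaluation = "high",  diag = "high",       plan = "high", nonfact = "high"
)

#' Map a clinical role to its subjectivity tier
#'
#' The mapping is total (every role has a tier) and surjective onto the
#' three tiers.
#'
#' @param role Character vector of role names.
#' @return Character vector of tiers, same length as `role`.
#' @export
#' @examples
#' role_tier("diag")
role_tier <- function(role) {
  bad <- setdiff(role, names(.ROLE_TIER))
  if (length(bad)) {
    stop("unknown clinical role(s): ", paste(bad, collapse = ", "))
  }
  unname(.ROLE_TIER[role])
}

#' Effective subjectivity for aggregation
#'
#' Segments flagged `probable` are treated as high subjectivity regardless
#' of the tier implied by their role, because probabilistic statements are
#' subjective by nature.
#'
#' @param subjectivity Character vector of tiers.
#' @param probable Logical vector.
#' @return Character vector of effective tiers.
#' @export
effective_subjectivity <- function(subjectivity, probable) {
  stopifnot(length(subjectivity) == length(probable))
  ifelse(probable, "high", subjectivity)
}

#' Construct a label set
#'
#' Bundles the three task labels carried by a segment. When `subjectivity`
#' is omitted it is derived from the role's tier, with the probable
#' override applied.
#'
#' @param role One of [clinical_roles()].
#' @param probable Logical flag (probabilistic expression).
#' @param subjectivity Optional explicit tier; defaults to
#'   `effective_subjectivity(role_tier(role), probable)`.
#' @return A named list with elements `subjectivity`, `role`, `probable`.
#' @export
#' @examples
#' label_set("result", probable = TRUE)$subjectivity  # "high"
label_set <- function(role, probable = FALSE, subjectivity = NULL) {
  stopifnot(length(role) == 1L, is.logical(probable), length(probable) == 1L)
  tier <- role_tier(role)
  if (is.null(subjectivity)) {
    subjectivity <- effective_subjectivity(tier, probable)
  }
  if (!subjectivity %in% subjectivity_tiers()) {
    stop("unknown subjectivity tier: ", subjectivity)
  }
  list(subjectivity = subjectivity, role = role, probable = isTRUE(probable))
}

.SOURCE_GROUPS <- c(
  patient_referral        = "past_history",
  outpatient_records      = "past_history",
  emergency_room_records  = "past_history",
  past_clinical_records   = "past_history",
  prescriptions           = "current_admission",
  nursing_records         = "current_admission",
  examination_results     = "current_admission",
  ecg_reports             = "current_admission",
  rehabilitation_reports  = "current_admission",
  surgical_notes          = "current_admission",
  anesthesia_records      = "current_admission",
  other_patients_records  = "others",
  other_documents         = "others",
  no_document             = "others"
)

#' Source-document labels for unsourced segments
#'
#' The 14 external-source labels an unsourced summary segment can be
#' attributed to, in three groups: past-history documents, documents of the
#' current admission, and others (including `no_document`, i.e. physician
#' memory or reasoning).
#'
#' @return Character vector of the 14 label names.
#' @export
source_doc_labels <- function() names(.SOURCE_GROUPS)

#' Group of a source-document label
#'
#' @param label Character vector of source-document labels.
#' @return One of `"past_history"`, `"current_admission"`, `"others"` per label.
#' @export
source_doc_group <- function(label) {
  bad <- setdiff(label, names(.SOURCE_GROUPS))
  if (length(bad)) {
    stop("unknown source document label(s): ", paste(bad, collapse = ", "))
  }
  unname(.SOURCE_GROUPS[label])
}
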