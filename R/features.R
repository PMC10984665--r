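core_concepts <- c("steatosis", "lobular_inflammation", "ballooning",
                   "steatohepatitis")

# report-level presence with conflict resolution: a concept asserted both
# present and absent in one report resolves to present (the rubric scores any
# assertion of presence; pathologists often negate in findings then affirm
# focally in the impression), with a conflict flag for audit
concept_presence <- function(mentions) {
  concepts <- unique(mentions$concept_id)
  present <- vapply(concepts, function(cc) {
    any(mentions$assertion[mentions$concept_id == cc] == "present")
  }, logical(1))
  conflict <- vapply(concepts, function(cc) {
    a <- mentions$assertion[mentions$concept_id == cc]
    any(a == "present") && any(a == "absent")
  }, logical(1))
  list(present = concepts[present], conflict = concepts[conflict],
       absent = concepts[vapply(concepts, function(cc) {
         all(mentions$assertion[mentions$concept_id == cc] == "absent")
       }, logical(1))])
}

#' Derive the report-level MASLD histology feature set
#'
#' Collapses concept mentions into the four core MASLD booleans plus cirrhosis
#' assertion under the scoring rubric: a feature is true iff at least one
#' present-asserted mention of that concept exists (after conflict
#' resolution); omissions are recorded as absent. Portal inflammation and its
#' synonyms never count as lobular inflammation, whereas lobular or zone-3
#' inflammation does (zone-3 surface forms are lobular-inflammation lexicon
#' entries).
#'
#' @param mentions asserted mentions from one report ([extract_mentions()]).
#' @param report_id report identifier.
#' @return list of class `histology_features`: `report_id`, `steatosis`,
#'   `lobular_inflammation`, `ballooning`, `mash_asserted`,
#'   `cirrhosis_asserted`, `conflict_flags`, `coincident_diseases`.
#' @export
derive_feature_set <- function(mentions, report_id = NA_character_) {
  pres <- concept_presence(mentions)
  structure(
    list(
      report_id = report_id,
      steatosis = "steatosis" %in% pres$present,
      lobular_inflammation = "lobular_inflammation" %in% pres$present,
      ballooning = "ballooning" %in% pres$present,
      mash_asserted = "steatohepatitis" %in% pres$present,
      cirrhosis_asserted = "cirrhosis" %in% pres$present,
      conflict_flags = pres$conflict,
      coincident_diseases = detect_coincident_disease(mentions)
    ),
    class = "histology_features"
  )
}

#' Detect coincident liver diseases
#'
#' Returns the present-asserted coincident diseases mentioned in a report
#' (viral hepatitis, autoimmune hepatitis, PBC/PSC, iron overload, granulomas,
#' ...), used to flag biopsies where steatosis coexists with a second disease.
#' Negated disease mentions are excluded. Detection is report-text-only.
#'
#' @param mentions asserted mentions from one report.
#' @param prefix concept-id prefix marking disease entries in the lexicon.
#' @return character vector of disease names (lexicon ids without the prefix).
#' @export
detect_coincident_disease <- function(mentions, prefix = "coincident:") {
  sel <- startsWith(mentions$concept_id, prefix) &
    mentions$assertion == "present"
  unique(substring(mentions$concept_id[sel], nchar(prefix) + 1L))
}
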