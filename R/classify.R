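#' Classification policy switches
#'
#' Knobs controlling deliberately-open corners of the report-level MASLD
#' classification:
#'
#' * `promote_bland_fibrosis` — whether steatosis with stage F1-F3 fibrosis
#'   but *no* inflammatory/ballooning/steatohepatitis feature is promoted to
#'   MASH by the stage-supersedes rule. Default `FALSE`: the supersede rule
#'   requires at least one MASH co-feature, and bland fibrotic steatosis
#'   stays simple steatosis with an audit note.
#' * `unstaged_mash_stage` — stage assigned when MASH is present but fibrosis
#'   could not be staged (e.g. only an Ishak-scale statement). Default `"F0"`
#'   (omission scored as absent), with an audit note.
#' * `borderline_mash_counts` — whether a "borderline steatohepatitis"
#'   assertion sets the MASH-asserted feature. Default `TRUE` (diminutives
#'   are scored as present).
#'
#' @param promote_bland_fibrosis logical.
#' @param unstaged_mash_stage `"F0"`..`"F3"`.
#' @param borderline_mash_counts logical.
#' @return list of class `masld_policy`.
#' @export
masld_policy <- function(promote_bland_fibrosis = FALSE,
                         unstaged_mash_stage = "F0",
                         borderline_mash_counts = TRUE) {
  stopifnot(unstaged_mash_stage %in% paste0("F", 0:3))
  structure(
    list(promote_bland_fibrosis = promote_bland_fibrosis,
         unstaged_mash_stage = unstaged_mash_stage,
         borderline_mash_counts = borderline_mash_counts),
    class = "masld_policy"
  )
}

#' Classify a report into a MASLD category
#'
#' Combines the histology feature set and fibrosis assessment into the
#' report-level category used for cohort strata: `no_steatosis`,
#' `simple_steatosis`, `mash_f0`..`mash_f3`, `cirrhosis_f4`.
#'
#' MASH is positive when the pathologist asserted steatohepatitis, or all
#' three elements (steatosis, lobular inflammation, ballooning) are present,
#' or — the stage-supersedes rule — fibrosis is staged F1-F3 and at least one
#' of lobular inflammation, ballooning, or a steatohepatitis assertion is
#' present (so steatosis + lobular inflammation + F2 is MASH/F2 despite
#' absent ballooning). F4/cirrhosis overrides everything given steatosis.
#' A steatohepatitis assertion implies steatosis (audit-noted) — the
#' summative diagnosis subsumes its defining feature.
#'
#' Steatotic non-MASH reports with exactly one MASH co-feature are marked
#' borderline (`ballooning_only` or `inflammation_only`); see
#' [apply_borderline_policy()].
#'
#' @param features a [derive_feature_set()] result.
#' @param fibrosis a [resolve_fibrosis_stage()] result.
#' @param policy a [masld_policy()].
#' @return list of class `masld_label`: `report_id`, `category`, `borderline`
#'   (`none`, `ballooning_only`, `inflammation_only`), `mash`,
#'   `fibrosis_stage`, `audit_notes`, `cohort_excluded`.
#' @export
classify_report <- function(features, fibrosis, policy = masld_policy()) {
  notes <- character(0)
  steat <- features$steatosis
  mash_assert <- features$mash_asserted
  if (mash_assert && !steat) {
    steat <- TRUE
    notes <- c(notes, "steatosis_implied_by_mash_assertion")
  }

  stage_lab <- fibrosis$resolved_stage
  fnum <- if (stage_lab == "unstaged") NA_integer_ else
    as.integer(sub("^F", "", stage_lab))

  infl <- features$lobular_inflammation
  ball <- features$ballooning
  supersede_feature <- infl || ball || mash_assert
  mash <- mash_assert ||
    (infl && ball) ||
    (!is.na(fnum) && fnum %in% 1:3 &&
       (supersede_feature || policy$promote_bland_fibrosis))

  borderline <- "none"
  if (!steat) {
    category <- "no_steatosis"
    mash <- FALSE
  } else if (!is.na(fnum) && fnum == 4L) {
    category <- "cirrhosis_f4"
  } else if (mash) {
    eff <- fnum
    if (is.na(eff)) {
      eff <- as.integer(sub("^F", "", policy$unstaged_mash_stage))
      notes <- c(notes, "unstaged_fibrosis_defaulted")
    }
    if (!supersede_feature && !(infl && ball) && !mash_assert) {
      notes <- c(notes, "mash_promoted_by_stage_alone")
    }
    category <- paste0("mash_f", eff)
  } else {
    category <- "simple_steatosis"
    if (ball && !infl) borderline <- "ballooning_only"
    if (infl && !ball) borderline <- "inflammation_only"
    if (!is.na(fnum) && fnum %in% 1:3 && !supersede_feature) {
      notes <- c(notes, "fibrosis_without_mash_features")
    }
  }

  structure(
    list(report_id = features$report_id, category = category,
         borderline = borderline, mash = mash,
         fibrosis_stage = stage_lab, audit_notes = notes,
         cohort_excluded = FALSE),
    class = "masld_label"
  )
}

#' Apply the borderline-MASH cohort policy
#'
#' In the primary analysis, steatotic biopsies with exactly one MASH
#' co-feature (ballooning without lobular inflammation, or lobular
#' inflammation without ballooning) are excluded from the cohort strata and
#' flagged. In the sensitivity analysis, ballooning-only biopsies are
#' categorized as MASH/F0 and inflammation-only biopsies as simple steatosis.
#'
#' @param label a [classify_report()] result.
#' @param mode `"primary"` or `"sensitivity"`.
#' @return the updated `masld_label`.
#' @export
apply_borderline_policy <- function(label, mode = c("primary", "sensitivity")) {
  mode <- match.arg(mode)
  if (label$borderline == "none") return(label)
  if (mode == "primary") {
    label$cohort_excluded <- TRUE
    label$audit_notes <- c(label$audit_notes, "borderline_excluded_primary")
  } else {
    if (label$borderline == "ballooning_only") {
      label$category <- "mash_f0"
      label$mash <- TRUE
      label$audit_notes <- c(label$audit_notes,
                             "borderline_ballooning_recoded_mash_f0")
    } else {
      label$category <- "simple_steatosis"
      label$audit_notes <- c(label$audit_notes,
                             "borderline_inflammation_kept_simple_steatosis")
    }
  }
  label
}

#' Annotate a single pathology report end-to-end
#'
#' Runs the full pipeline on one raw report: NFKC normalization, boilerplate
#' stripping, parenchymal-biopsy screening, concept extraction with negation,
#' feature derivation, fibrosis staging, and MASLD classification.
#'
#' @param report list/one-row data.frame with `report_id` and `text`.
#' @param config a [masld_config()].
#' @return list of class `masld_annotation` with elements `section`, `screen`,
#'   `extraction`, `features`, `fibrosis`, `label` (the last three `NULL` for
#'   screened-out reports).
#' @export
annotate_report <- function(report, config = masld_config()) {
  section <- strip_report_boilerplate(report, config$boilerplate)
  screen <- screen_parenchymal_biopsy(section, config$screen, config$negation)
  out <- list(section = section, screen = screen, extraction = NULL,
              features = NULL, fibrosis = NULL, label = NULL)
  if (screen$is_parenchymal_liver_biopsy) {
    ex <- extract_mentions(section$diagnostic_text, config$lexicon,
                           config$negation)
    features <- derive_feature_set(ex$mentions, report$report_id)
    fibrosis <- assess_fibrosis(ex, features$cirrhosis_asserted,
                                report$report_id)
    out$extraction <- ex
    out$features <- features
    out$fibrosis <- fibrosis
    out$label <- classify_report(features, fibrosis, config$policy)
  }
  structure(out, class = "masld_annotation")
}

#' Annotate a corpus of reports
#'
#' Vectorized [annotate_report()] returning one row per report with the
#' validated concept columns (the four core features, cirrhosis, fibrosis
#' stage), the MASLD category, borderline status and audit notes — the layout
#' consumed by the validation harness and by cohort construction.
#'
#' @param reports data.frame with `report_id` and `text` columns.
#' @param config a [masld_config()].
#' @param borderline_mode passed to [apply_borderline_policy()].
#' @return data.frame, one row per input report.
#' @export
annotate_corpus <- function(reports, config = masld_config(),
                            borderline_mode = c("primary", "sensitivity")) {
  borderline_mode <- match.arg(borderline_mode)
  validate_reports(reports)
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    ann <- annotate_report(reports[i, , drop = FALSE], config)
    if (!ann$screen$is_parenchymal_liver_biopsy) {
      return(data.frame(
        report_id = reports$report_id[i], screened_in = FALSE,
        exclusion_reason = ann$screen$exclusion_reason,
        steatosis = NA, lobular_inflammation = NA, ballooning = NA,
        steatohepatitis = NA, cirrhosis = NA,
        fibrosis_stage = NA_character_, category = NA_character_,
        borderline = NA_character_, cohort_excluded = NA,
        coincident_diseases = NA_character_, audit_notes = NA_character_,
        stringsAsFactors = FALSE
      ))
    }
    label <- apply_borderline_policy(ann$label, borderline_mode)
    data.frame(
      report_id = reports$report_id[i], screened_in = TRUE,
      exclusion_reason = "none",
      steatosis = ann$features$steatosis,
      lobular_inflammation = ann$features$lobular_inflammation,
      ballooning = ann$features$ballooning,
      steatohepatitis = label$mash,
      cirrhosis = ann$features$cirrhosis_asserted,
      fibrosis_stage = label$fibrosis_stage,
      category = label$category,
      borderline = label$borderline,
      cohort_excluded = label$cohort_excluded,
      coincident_diseases = paste(ann$features$coincident_diseases,
                                  collapse = ";"),
      audit_notes = paste(label$audit_notes, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
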