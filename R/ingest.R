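#' Read a pathology-report corpus
#'
#' Reads reports from JSONL (one object per line) or CSV. Both formats carry
#' the columns `report_id`, `patient_id`, `report_date` (ISO-8601),
#' `hospital`, `text`.
#'
#' @param path file path; format inferred from the extension unless `format`
#'   is given.
#' @param format `"jsonl"` or `"csv"`.
#' @return data.frame, one row per report.
#' @export
read_reports <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(r[c("report_id", "patient_id", "report_date", "hospital",
                        "text")], stringsAsFactors = FALSE)
    }))
  }
  validate_reports(df)
  df
}

validate_reports <- function(df) {
  needed <- c("report_id", "text")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("report corpus missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$report_id)) {
    stop("duplicate report_id in corpus: ",
         paste(unique(df$report_id[duplicated(df$report_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$report_id)) || any(!nzchar(df$text))) {
    stop("report_id and text must be non-empty", call. = FALSE)
  }
  invisible(df)
}

marker_regex <- function(markers) {
  pats <- vapply(markers[order(-nchar(markers))], function(m) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", m)
    gsub("\\s+", "\\\\s+", esc)
  }, character(1))
  paste0("\\b(?:", paste(pats, collapse = "|"), ")\\s*:")
}

# footers are signature lines, not colon-terminated headings
footer_regex <- function(markers) {
  pats <- vapply(markers[order(-nchar(markers))], function(m) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", m)
    gsub("\\s+", "\\\\s+", esc)
  }, character(1))
  paste0("\\b(?:", paste(pats, collapse = "|"), ")\\b")
}

first_match <- function(pattern, text) {
  m <- regexpr(pattern, text, perl = TRUE, ignore.case = TRUE)
  if (m[1] == -1L) return(NULL)
  c(start = m[1], end = m[1] + attr(m, "match.length"))  # 1-based, end exclusive
}

#' Strip non-diagnostic boilerplate from a report
#'
#' Removes headers (accession/demographics/clinical context), the gross
#' specimen description, and signature footers, leaving only the diagnostic
#' text (findings and impressions). Section detection is by configurable
#' heading-marker lists parsed in order of appearance: header and gross
#' material precede the diagnosis heading, footers follow it.
#'
#' Text is NFKC-normalized first; all spans are 0-based half-open character
#' intervals into the normalized source text. The operation is idempotent:
#' applying it to its own diagnostic output returns that text unchanged.
#'
#' @param report a one-row data.frame or list with `report_id` and `text`.
#' @param rules see [boilerplate_rules()].
#' @return list of class `diagnostic_section` with `report_id`,
#'   `diagnostic_text`, `removed_spans` (data.frame `label`, `start`, `end`),
#'   and `no_diagnostic_section` (TRUE when header material was found but no
#'   recognizable diagnosis section; such reports are flagged, not dropped).
#' @export
strip_report_boilerplate <- function(report, rules = boilerplate_rules()) {
  text <- normalize_text(report$text)
  n <- nchar(text)
  spans <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)

  diag_m <- first_match(marker_regex(rules$diagnosis_markers), text)
  head_m <- first_match(marker_regex(rules$header_markers), text)
  gross_m <- first_match(marker_regex(rules$gross_markers), text)
  foot_m <- first_match(footer_regex(rules$footer_markers), text)

  if (is.null(diag_m)) {
    if (is.null(head_m) && is.null(foot_m) && is.null(gross_m)) {
      # identity case: the report is all diagnosis
      out <- trim_span(text, 1L, n + 1L)
      return(new_diagnostic_section(report$report_id, out$text, spans, FALSE,
                                    out$start - 1L, out$end - 1L))
    }
    return(new_diagnostic_section(report$report_id, "", spans, TRUE, 0L, 0L))
  }

  body_start <- diag_m[["end"]]                   # 1-based, after "DIAGNOSIS:"
  foot_start <- if (!is.null(foot_m) && foot_m[["start"]] > diag_m[["start"]]) {
    foot_m[["start"]]
  } else {
    n + 1L
  }

  # header region before the diagnosis heading, split at the gross marker
  if (diag_m[["start"]] > 1L) {
    if (!is.null(gross_m) && gross_m[["start"]] < diag_m[["start"]]) {
      if (gross_m[["start"]] > 1L) {
        spans <- rbind(spans, data.frame(label = "header", start = 0L,
                                         end = gross_m[["start"]] - 1L))
      }
      spans <- rbind(spans, data.frame(label = "gross",
                                       start = gross_m[["start"]] - 1L,
                                       end = diag_m[["start"]] - 1L))
    } else {
      spans <- rbind(spans, data.frame(label = "header", start = 0L,
                                       end = diag_m[["start"]] - 1L))
    }
  }
  # the diagnosis heading itself is boilerplate
  spans <- rbind(spans, data.frame(label = "header",
                                   start = diag_m[["start"]] - 1L,
                                   end = body_start - 1L))
  if (foot_start <= n) {
    spans <- rbind(spans, data.frame(label = "footer", start = foot_start - 1L,
                                     end = n))
  }

  out <- trim_span(text, body_start, foot_start)
  new_diagnostic_section(report$report_id, out$text, spans,
                         !nzchar(out$text), out$start - 1L, out$end - 1L)
}

# trim whitespace off a [start, end) 1-based span, returning text + bounds
trim_span <- function(text, start, end) {
  seg <- substr(text, start, end - 1L)
  lead <- regmatches(seg, regexpr("^\\s*", seg))
  trail <- regmatches(seg, regexpr("\\s*$", seg))
  list(text = trimws(seg),
       start = start + nchar(lead),
       end = end - nchar(trail))
}

new_diagnostic_section <- function(report_id, text, spans, flagged,
                                   start0, end0) {
  structure(
    list(report_id = report_id, diagnostic_text = text,
         removed_spans = spans, no_diagnostic_section = flagged,
         diagnostic_span = c(start = start0, end = end0)),
    class = "diagnostic_section"
  )
}

#' Screen a diagnostic section for a parenchymal liver biopsy
#'
#' Excludes reports describing biopsies of other organs that merely mention
#' the liver, liver fine-needle aspirations, and biopsies of hepatic tumors.
#' When several exclusion cues fire the fixed precedence is
#' `non_liver_organ` > `tumor_biopsy` > `fine_needle_aspiration` (specimen
#' organ is the strongest signal). A section with no liver/hepatic mention at
#' all is excluded as `no_liver_mention`. Tumor terms are assertion-aware:
#' "No malignancy identified" never excludes a report.
#'
#' @param section a [strip_report_boilerplate()] result.
#' @param rules see [screen_rules()].
#' @param negation negation rules used for assertion-aware tumor matching.
#' @return list of class `biopsy_screen` with `report_id`,
#'   `is_parenchymal_liver_biopsy`, `exclusion_reason`.
#' @export
screen_parenchymal_biopsy <- function(section, rules = screen_rules(),
                                      negation = negation_rules()) {
  text <- section$diagnostic_text
  reason <- "none"

  liver_pat <- paste0("\\b(?:", paste(rules$liver_terms, collapse = "|"), ")\\b")
  if (!nzchar(text) || !grepl(liver_pat, text, perl = TRUE, ignore.case = TRUE)) {
    reason <- "no_liver_mention"
  } else {
    organ_pat <- paste0(
      "\\b(?:",
      paste(gsub("\\s+", "\\\\s+", rules$non_liver_organs), collapse = "|"),
      ")\\b\\s*[,:]"
    )
    fna_pat <- paste0(
      "\\b(?:",
      paste(gsub("\\s+", "(?:\\\\s|-)+", rules$fna_terms), collapse = "|"),
      ")\\b"
    )
    if (grepl(organ_pat, text, perl = TRUE, ignore.case = TRUE)) {
      reason <- "non_liver_organ"
    } else if (tumor_asserted(text, rules$tumor_terms, negation)) {
      reason <- "tumor_biopsy"
    } else if (grepl(fna_pat, text, perl = TRUE, ignore.case = TRUE)) {
      reason <- "fine_needle_aspiration"
    }
  }

  structure(
    list(report_id = section$report_id,
         is_parenchymal_liver_biopsy = (reason == "none"),
         exclusion_reason = reason),
    class = "biopsy_screen"
  )
}

# match tumor phrases through the mention/negation machinery so that negated
# tumor language does not exclude a report
tumor_asserted <- function(text, tumor_terms, negation) {
  lex <- data.frame(concept_id = "tumor", surface = tumor_terms,
                    stringsAsFactors = FALSE)
  lex$pattern <- vapply(lex$surface, compile_surface, character(1))
  sents <- segment_sentences(text)
  mentions <- match_lexicon_mentions(text, sents, lex)
  if (nrow(mentions) == 0L) return(FALSE)
  mentions <- assign_assertions(mentions, text, sents, negation)
  any(mentions$assertion == "present")
}
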