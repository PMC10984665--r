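roman_map <- c(i = 1L, ii = 2L, iii = 3L, iv = 4L, v = 5L, vi = 6L)

stage_token <- function(tok) {
  tok <- tolower(tok)
  if (grepl("^[0-9]+$", tok)) return(as.integer(tok))
  if (tok %in% names(roman_map)) return(unname(roman_map[tok]))
  NA_integer_
}

# ordered explicit-stage patterns; earlier patterns consume their span so
# "stage 3 of 4" is not re-read as "stage 3"
stage_patterns <- list(
  list(kind = "range",
       pat = "\\b(?:fibrosis\\s+)?stage\\s+f?\\s*([0-9]+|[ivx]+)\\s*(?:-|–|—|to)\\s*f?\\s*([0-9]+|[ivx]+)\\b"),
  list(kind = "range",
       pat = "\\bf\\s*([0-9]+)\\s*(?:-|–|—|to)\\s*f?\\s*([0-9]+)\\b"),
  list(kind = "frac",
       pat = "\\b(?:fibrosis\\s+)?stage\\s+f?\\s*([0-9]+|[ivx]+)\\s+(?:of|out\\s+of)\\s+([0-9]+)\\b"),
  list(kind = "frac",
       pat = "\\b(?:stage|fibrosis[,:]?)\\s*f?\\s*([0-9]+)\\s*/\\s*([0-9]+)\\b"),
  list(kind = "single",
       pat = "\\b(?:fibrosis\\s+)?stage\\s+(?:f\\s*)?([0-9]+|[ivx]+)\\b"),
  list(kind = "single",
       pat = "\\bf\\s?([0-9]+)\\b")
)

#' Parse explicit fibrosis-stage statements
#'
#' Recognizes explicit pathologist stage assignments: "stage N",
#' "stage N of M", "N/M", "F N", and ranges "N-M" / "N to M" (each bound
#' recorded separately, so the highest-stage rule can apply), with Arabic or
#' Roman numerals. The denominator is recorded when stated (4 for MASH CRN,
#' 6 for Ishak-style) and `unknown` otherwise. Stage tokens outside 0-6 raise
#' a malformed-stage flag and the mention is ignored.
#'
#' @param sentences a [segment_sentences()] data.frame or character vector of
#'   sentence texts.
#' @return data.frame with columns `stage`, `denominator` (4, 6 or NA for
#'   unknown), `sentence_index`, `start`, `end` (0-based, sentence-relative),
#'   `malformed` (logical).
#' @export
parse_explicit_stages <- function(sentences) {
  if (is.character(sentences)) {
    sentences <- data.frame(sentence_index = seq_along(sentences),
                            text = sentences, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(sentences))) {
    stext <- sentences$text[i]
    masked <- stext  # consumed spans overwritten so later patterns skip them
    for (sp in stage_patterns) {
      repeat {
        m <- regexpr(sp$pat, masked, perl = TRUE, ignore.case = TRUE)
        if (m[1] == -1L) break
        s1 <- m[1]; e1 <- m[1] + attr(m, "match.length") - 1L
        frag <- substr(stext, s1, e1)
        g <- regmatches(frag, regexec(sp$pat, frag, perl = TRUE,
                                      ignore.case = TRUE))[[1]]
        toks <- g[-1]
        stages <- if (sp$kind == "range") {
          vapply(toks[1:2], stage_token, integer(1))
        } else {
          stage_token(toks[1])
        }
        denom <- if (sp$kind == "frac") as.integer(toks[2]) else NA_integer_
        for (stg in stages) {
          bad <- is.na(stg) || stg > 6L
          out[[length(out) + 1L]] <- data.frame(
            stage = if (bad) NA_integer_ else stg,
            denominator = if (!is.na(denom) && denom %in% c(4L, 6L)) denom
                          else NA_integer_,
            sentence_index = sentences$sentence_index[i],
            start = s1 - 1L, end = e1,
            malformed = bad, stringsAsFactors = FALSE
          )
        }
        substr(masked, s1, e1) <- strrep(" ", e1 - s1 + 1L)

      }
    }
  }
  if (!length(out)) {
    return(data.frame(stage = integer(0), denominator = integer(0),
                      sentence_index = integer(0), start = integer(0),
                      end = integer(0), malformed = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$sentence_index, res$start), , drop = FALSE]
}

#' Detect MASH CRN fibrosis components
#'
#' Sets component flags from present-asserted fibrosis-pattern mentions:
#' perisinusoidal/pericellular zone-3 fibrosis, zone-1/periportal fibrosis,
#' bridging fibrosis, and nodule formation. Negated components never set a
#' flag. `fibrosis_negated` is true iff generic fibrosis is absent-asserted
#' and no component is present.
#'
#' @param mentions asserted mentions from one report.
#' @return list with logical flags `perisinusoidal_zone3`, `zone1_periportal`,
#'   `bridging`, `nodularity`, and `fibrosis_negated`.
#' @export
detect_fibrosis_components <- function(mentions) {
  pres <- concept_presence(mentions)
  flags <- list(
    perisinusoidal_zone3 = "perisinusoidal_fibrosis" %in% pres$present,
    zone1_periportal = "periportal_fibrosis" %in% pres$present,
    bridging = "bridging_fibrosis" %in% pres$present,
    nodularity = "nodularity" %in% pres$present
  )
  flags$fibrosis_negated <- ("fibrosis_generic" %in% pres$absent) &&
    !any(unlist(flags[1:4]))
  flags
}

#' Resolve the MASH CRN fibrosis stage for a report
#'
#' Combines explicit stage statements and component evidence under the
#' highest-stage rule: candidate stages are all in-scale explicit stages
#' (denominator 4 or unstated, stage 0-4), the component-mapped stages
#' (perisinusoidal zone-3 alone = F1; perisinusoidal plus zone-1 = F2;
#' zone-1 alone = F1-equivalent, flagged; bridging = F3; nodularity = F4),
#' and F4 whenever cirrhosis is asserted. The resolved stage is the maximum
#' candidate, so "F1-F2" resolves to F2 and explicit F2 plus bridging to F3.
#'
#' With no candidates: F0 with source `negation` when fibrosis was explicitly
#' negated, otherwise F0 with source `omission` (omissions are recorded as
#' absent). Ishak-style "of 6" stages are never silently remapped to the CRN
#' scale: with no other evidence the report is `unstaged` with a
#' scale-mismatch flag.
#'
#' @param explicit_stages [parse_explicit_stages()] output.
#' @param components [detect_fibrosis_components()] output.
#' @param cirrhosis_asserted report-level cirrhosis assertion.
#' @param report_id report identifier.
#' @return list of class `fibrosis_assessment`: `report_id`,
#'   `explicit_stages`, `components`, `fibrosis_negated`, `resolved_stage`
#'   ("F0".."F4" or "unstaged"), `stage_source` (explicit / components /
#'   negation / omission), `flags` (character: `scale_mismatch`,
#'   `zone1_only`, `malformed_stage`).
#' @export
resolve_fibrosis_stage <- function(explicit_stages, components,
                                   cirrhosis_asserted = FALSE,
                                   report_id = NA_character_) {
  flags <- character(0)
  if (nrow(explicit_stages) && any(explicit_stages$malformed)) {
    flags <- c(flags, "malformed_stage")
  }
  ok <- explicit_stages[!explicit_stages$malformed, , drop = FALSE]
  in_scale <- ok[(is.na(ok$denominator) | ok$denominator == 4L) &
                   ok$stage <= 4L, , drop = FALSE]
  off_scale <- ok[!is.na(ok$denominator) & ok$denominator == 6L |
                    ok$stage > 4L, , drop = FALSE]
  if (nrow(off_scale)) flags <- c(flags, "scale_mismatch")

  comp_stage <- integer(0)
  if (components$perisinusoidal_zone3 && components$zone1_periportal) {
    comp_stage <- c(comp_stage, 2L)
  } else if (components$perisinusoidal_zone3) {
    comp_stage <- c(comp_stage, 1L)
  } else if (components$zone1_periportal) {
    # zone-1-only fibrosis: F1-equivalent candidate (CRN 1c analog), audited;
    # mapping it to F2 would overstage since F2 requires both zones
    comp_stage <- c(comp_stage, 1L)
    flags <- c(flags, "zone1_only")
  }
  if (components$bridging) comp_stage <- c(comp_stage, 3L)
  if (components$nodularity) comp_stage <- c(comp_stage, 4L)
  if (cirrhosis_asserted) comp_stage <- c(comp_stage, 4L)

  explicit_cand <- in_scale$stage
  candidates <- c(explicit_cand, comp_stage)

  if (length(candidates)) {
    resolved <- max(candidates)
    source <- if (length(explicit_cand) && max(explicit_cand) == resolved) {
      "explicit"
    } else {
      "components"
    }
    stage_lab <- paste0("F", resolved)
  } else if (nrow(off_scale)) {
    resolved <- NA_integer_
    source <- "explicit"
    stage_lab <- "unstaged"
  } else if (isTRUE(components$fibrosis_negated)) {
    resolved <- 0L
    source <- "negation"
    stage_lab <- "F0"
  } else {
    resolved <- 0L
    source <- "omission"
    stage_lab <- "F0"
  }

  structure(
    list(report_id = report_id, explicit_stages = explicit_stages,
         components = components[c("perisinusoidal_zone3", "zone1_periportal",
                                   "bridging", "nodularity")],
         fibrosis_negated = isTRUE(components$fibrosis_negated),
         resolved_stage = stage_lab, stage_source = source,
         flags = unique(flags)),
    class = "fibrosis_assessment"
  )
}

#' Assess fibrosis from extracted mentions and sentences
#'
#' Convenience wrapper combining [parse_explicit_stages()],
#' [detect_fibrosis_components()] and [resolve_fibrosis_stage()].
#'
#' @param extraction an [extract_mentions()] result.
#' @param cirrhosis_asserted report-level cirrhosis assertion.
#' @param report_id report identifier.
#' @return a `fibrosis_assessment`.
#' @export
assess_fibrosis <- function(extraction, cirrhosis_asserted = FALSE,
                            report_id = NA_character_) {
  resolve_fibrosis_stage(
    parse_explicit_stages(extraction$sentences),
    detect_fibrosis_components(extraction$mentions),
    cirrhosis_asserted = cirrhosis_asserted,
    report_id = report_id
  )
}
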