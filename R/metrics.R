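#' The validated concepts
#'
#' The concepts scored by the validation harness: the four core MASLD
#' features, cirrhosis, and the five fibrosis stages (scored one-vs-rest).
#'
#' @return character vector of concept ids.
#' @export
validated_concepts <- function() {
  c("steatosis", "lobular_inflammation", "ballooning", "steatohepatitis",
    "cirrhosis", paste0("F", 0:4))
}

concept_indicator <- function(df, concept) {
  if (concept %in% paste0("F", 0:4)) {
    if (!"fibrosis_stage" %in% names(df)) {
      stop("fibrosis_stage column required for stage concept ", concept,
           call. = FALSE)
    }
    return(!is.na(df$fibrosis_stage) & df$fibrosis_stage == concept)
  }
  if (!concept %in% names(df)) {
    stop("column '", concept, "' not found", call. = FALSE)
  }
  as.logical(df[[concept]])
}

#' Tabulate a confusion matrix for one concept
#'
#' Compares predicted and gold labels for one of the validated concepts
#' (the four core MASLD features, cirrhosis, or a fibrosis stage F0-F4;
#' stages are binarized one-vs-rest). Reports present in only one of the two
#' sets are a hard error listing the offending ids.
#'
#' @param predicted,gold data.frames with `report_id` plus concept columns
#'   (logical) and/or `fibrosis_stage`.
#' @param concept one of [validated_concepts()].
#' @return list of class `confusion_counts`: `concept`, `tp`, `fp`, `fn`,
#'   `tn`, `n` (with `tp+fp+fn+tn == n`).
#' @export
tabulate_confusion <- function(predicted, gold, concept) {
  stopifnot(concept %in% validated_concepts())
  only_p <- setdiff(predicted$report_id, gold$report_id)
  only_g <- setdiff(gold$report_id, predicted$report_id)
  if (length(only_p) || length(only_g)) {
    stop("report_id mismatch between predicted and gold; only in predicted: [",
         paste(only_p, collapse = ", "), "]; only in gold: [",
         paste(only_g, collapse = ", "), "]", call. = FALSE)
  }
  gold <- gold[match(predicted$report_id, gold$report_id), , drop = FALSE]
  p <- concept_indicator(predicted, concept)
  g <- concept_indicator(gold, concept)
  if (anyNA(p) || anyNA(g)) {
    stop("NA labels for concept ", concept,
         "; screen out non-biopsy reports before validation", call. = FALSE)
  }
  structure(
    list(concept = concept,
         tp = sum(p & g), fp = sum(p & !g),
         fn = sum(!p & g), tn = sum(!p & !g),
         n = length(p)),
    class = "confusion_counts"
  )
}

ratio_pct <- function(num, den) {
  if (den == 0) NA_real_ else 100 * num / den
}

#' F1 score from precision and recall
#'
#' The harmonic mean of precision (PPV) and recall (sensitivity), on the
#' percentage scale. Useful for worked examples computed from a published
#' table's displayed precision/recall.
#'
#' @param ppv,sensitivity percentages.
#' @return percentage, or `NA` when both inputs are zero or either is `NA`.
#' @export
f1_from_precision_recall <- function(ppv, sensitivity) {
  ifelse(is.na(ppv) | is.na(sensitivity) | (ppv + sensitivity) == 0,
         NA_real_, 2 * ppv * sensitivity / (ppv + sensitivity))
}

#' Compute performance metrics from confusion counts
#'
#' Sensitivity (recall), specificity, PPV (precision), NPV and F1 on the
#' percentage scale, plus support. Support is the count of gold-positive
#' reports (`tp + fn`) — the actual number of occurrences of the concept in
#' the validation set. Undefined ratios (zero denominator) are reported as
#' `NA`, never 0. Full precision is retained; display rounding to one decimal
#' is applied by [format_performance()].
#'
#' @param cc a [tabulate_confusion()] result.
#' @return one-row data.frame: `concept`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `f1`, `support`, `n`.
#' @export
compute_performance <- function(cc) {
  sens <- ratio_pct(cc$tp, cc$tp + cc$fn)
  spec <- ratio_pct(cc$tn, cc$tn + cc$fp)
  ppv <- ratio_pct(cc$tp, cc$tp + cc$fp)
  npv <- ratio_pct(cc$tn, cc$tn + cc$fn)
  data.frame(
    concept = cc$concept, sensitivity = sens, specificity = spec,
    ppv = ppv, npv = npv, f1 = f1_from_precision_recall(ppv, sens),
    support = cc$tp + cc$fn, n = cc$n, stringsAsFactors = FALSE
  )
}

#' Score a predicted corpus against gold labels
#'
#' One row per concept: sensitivity, specificity, PPV, NPV, F1 and support,
#' the layout of a published validation table.
#'
#' @param predicted,gold data.frames sharing `report_id`; see
#'   [tabulate_confusion()].
#' @param concepts concepts to score; default all ten validated concepts.
#' @return data.frame, one row per concept.
#' @export
performance_table <- function(predicted, gold, concepts = validated_concepts()) {
  do.call(rbind, lapply(concepts, function(cc) {
    compute_performance(tabulate_confusion(predicted, gold, cc))
  }))
}

#' Round a performance table for display
#'
#' @param tbl a [performance_table()] result.
#' @param digits decimals shown (the conventional display is one decimal).
#' @return data.frame with rounded metric columns.
#' @export
format_performance <- function(tbl, digits = 1) {
  for (col in c("sensitivity", "specificity", "ppv", "npv", "f1")) {
    tbl[[col]] <- round(tbl[[col]], digits)
  }
  tbl
}

#' List predicted/gold disagreements for audit
#'
#' @param predicted,gold data.frames sharing `report_id`.
#' @param concepts concepts to compare.
#' @return data.frame: `report_id`, `concept`, `predicted`, `gold`.
#' @export
validation_disagreements <- function(predicted, gold,
                                     concepts = validated_concepts()) {
  gold <- gold[match(predicted$report_id, gold$report_id), , drop = FALSE]
  out <- lapply(concepts, function(cc) {
    p <- concept_indicator(predicted, cc)
    g <- concept_indicator(gold, cc)
    bad <- which(p != g)
    if (!length(bad)) return(NULL)
    data.frame(report_id = predicted$report_id[bad], concept = cc,
               predicted = p[bad], gold = g[bad], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(report_id = character(0), concept = character(0),
                      predicted = logical(0), gold = logical(0))
  }
  out
}
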