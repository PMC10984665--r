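#' Segment diagnostic text into sentences
#'
#' Splits on sentence-terminating punctuation (`.`, `!`, `?`) and newlines,
#' while treating the period of a numbered list marker at the start of a line
#' ("1.", "2.") as part of the item, not a terminator — diagnosis lines are
#' routinely enumerated. Returned spans are ordered, non-overlapping, 0-based
#' half-open intervals covering all non-whitespace text.
#'
#' @param text diagnostic text (already NFKC-normalized).
#' @return data.frame with columns `sentence_index`, `start`, `end`, `text`.
#' @export
segment_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(sentence_index = integer(0), start = integer(0),
                      end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  # boundary after position i (1-based) means a sentence ends at i
  boundary <- logical(n)
  newline_at <- which(chars == "\n")
  boundary[newline_at] <- TRUE
  term_at <- which(chars %in% c(".", "!", "?"))
  for (p in term_at) {
    prev_nl <- newline_at[newline_at < p]
    line_start <- if (length(prev_nl)) max(prev_nl) + 1L else 1L
    before <- substr(text, line_start, p - 1L)
    if (grepl("^\\s*[0-9]+$", before)) next  # list marker "1."
    boundary[p] <- TRUE
  }
  boundary[n] <- TRUE

  ends <- which(boundary)
  starts <- c(1L, head(ends, -1L) + 1L)
  spans <- data.frame(start = starts, end = ends)  # 1-based inclusive
  # trim whitespace, drop empty segments
  out <- do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
    tr <- trim_span(text, spans$start[i], spans$end[i] + 1L)
    if (!nzchar(tr$text)) return(NULL)
    data.frame(start = tr$start - 1L, end = tr$end - 1L, text = tr$text,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(sentence_index = integer(0), start = integer(0),
                      end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(sentence_index = seq_len(nrow(out)), out,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_mentions <- function() {
  data.frame(concept_id = character(0), surface_text = character(0),
             start = integer(0), end = integer(0),
             sentence_index = integer(0), assertion = character(0),
             stringsAsFactors = FALSE)
}

#' Match lexicon concepts in diagnostic text
#'
#' Finds every lexicon surface form in the text (case-insensitive, word
#' bounded). Overlapping candidate matches are resolved longest-match-wins, so
#' "steatohepatitis" yields a steatohepatitis mention only, and "primary
#' biliary cirrhosis" is a coincident-disease mention rather than cirrhosis.
#' Ties on length break by earlier start, then lexicon order.
#'
#' @param text diagnostic text.
#' @param sentences [segment_sentences()] output for `text`.
#' @param lexicon [masld_lexicon()] data.frame.
#' @return data.frame of mentions: `concept_id`, `surface_text`, `start`,
#'   `end` (0-based half-open), `sentence_index`, `assertion` (`NA`, set by
#'   [assign_assertions()]).
#' @export
match_lexicon_mentions <- function(text, sentences, lexicon) {
  cand <- list()
  for (i in seq_len(nrow(lexicon))) {
    m <- gregexpr(lexicon$pattern[i], text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    keep <- len > 0L
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- data.frame(
      concept_id = lexicon$concept_id[i],
      start1 = as.integer(m[keep]), len = as.integer(len[keep]),
      lex_order = i, stringsAsFactors = FALSE
    )
  }
  if (!length(cand)) return(empty_mentions())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$len, cand$start1, cand$lex_order), , drop = FALSE]

  taken <- logical(nchar(text))
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start1[i]:(cand$start1[i] + cand$len[i] - 1L)
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      kept[i] <- TRUE
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start1), , drop = FALSE]

  sent_idx <- vapply(cand$start1, function(s0) {
    hit <- which(sentences$start < s0 & sentences$end >= s0)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))

  data.frame(
    concept_id = cand$concept_id,
    surface_text = substring(text, cand$start1, cand$start1 + cand$len - 1L),
    start = cand$start1 - 1L,
    end = cand$start1 + cand$len - 1L,
    sentence_index = sent_idx,
    assertion = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

trigger_matches <- function(sent_text, phrases) {
  if (!length(phrases)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- list()
  for (ph in phrases) {
    pat <- if (grepl("^[[:punct:]]$", ph)) {
      paste0("\\", ph)
    } else {
      paste0("\\b", gsub("\\s+", "\\\\s+", ph), "\\b")
    }
    m <- gregexpr(pat, sent_text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    out[[length(out) + 1L]] <- data.frame(
      start = as.integer(m), end = as.integer(m) + attr(m, "match.length")
    )
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

#' Assign present/absent assertions to concept mentions
#'
#' Trigger-based negation scoping, sentence-bounded. A mention is scored
#' absent iff it falls inside the scope of a trigger in its own sentence:
#' forward from a pre-trigger ("no", "without", "negative for", ...) to the
#' nearest scope terminator ("but", "however", ";", "."), or backward from a
#' post-trigger ("not identified", "is absent", ...) to the nearest preceding
#' terminator. Everything else is present. Diminutive qualifiers ("minimal",
#' "patchy", "borderline") never negate — the scoring rubric counts them as
#' presence. Double negation is not resolved (scored absent).
#'
#' @param mentions [match_lexicon_mentions()] output.
#' @param text the diagnostic text the mentions index into.
#' @param sentences [segment_sentences()] output.
#' @param rules [negation_rules()].
#' @return `mentions` with the `assertion` column set.
#' @export
assign_assertions <- function(mentions, text, sentences,
                              rules = negation_rules()) {
  if (nrow(mentions) == 0L) return(mentions)
  mentions$assertion <- "present"
  for (si in unique(mentions$sentence_index)) {
    if (is.na(si)) next
    srow <- sentences[sentences$sentence_index == si, ]
    stext <- srow$text
    offset <- srow$start  # 0-based start of sentence in text
    pre <- trigger_matches(stext, rules$pre_triggers)
    post <- trigger_matches(stext, rules$post_triggers)
    # a post-trigger that begins inside a longer pre-trigger (or vice versa)
    # is genuine only if it is not the same span; overlap is harmless here
    term <- trigger_matches(stext, rules$terminators)
    in_sent <- which(mentions$sentence_index == si)
    for (mi in in_sent) {
      # mention bounds relative to the sentence, 1-based
      ms <- mentions$start[mi] - offset + 1L
      me <- mentions$end[mi] - offset
      negated <- FALSE
      for (ti in seq_len(nrow(pre))) {
        sc_start <- pre$end[ti]
        after <- term$start[term$start >= pre$end[ti]]
        sc_end <- if (length(after)) min(after) else nchar(stext) + 1L
        if (ms >= sc_start && me < sc_end) { negated <- TRUE; break }
      }
      if (!negated) for (ti in seq_len(nrow(post))) {
        sc_end <- post$start[ti]
        before <- term$end[term$end <= post$start[ti]]
        sc_start <- if (length(before)) max(before) else 1L
        if (ms >= sc_start && me <= sc_end - 1L) { negated <- TRUE; break }
      }
      if (negated) mentions$assertion[mi] <- "absent"
    }
  }
  mentions
}

#' Extract asserted concept mentions from diagnostic text
#'
#' Convenience wrapper: segment sentences, match the lexicon, assign
#' assertions. Extraction is a pure function of (text, lexicon, rules):
#' identical inputs give byte-identical outputs.
#'
#' @param text diagnostic text (will be NFKC-normalized).
#' @param lexicon [masld_lexicon()].
#' @param negation [negation_rules()].
#' @return list with `text` (normalized), `sentences`, `mentions`.
#' @export
extract_mentions <- function(text, lexicon = masld_lexicon(),
                             negation = negation_rules()) {
  text <- normalize_text(text)
  sentences <- segment_sentences(text)
  mentions <- match_lexicon_mentions(text, sentences, lexicon)
  mentions <- assign_assertions(mentions, text, sentences, negation)
  list(text = text, sentences = sentences, mentions = mentions)
}
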