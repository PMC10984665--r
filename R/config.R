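#' Normalize report text
#'
#' Applies Unicode NFKC normalization. All downstream character spans are
#' 0-based half-open offsets into this normalized text, so offsets are
#' reproducible across report-text dialects.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  stringi::stri_trans_nfkc(x)
}

config_file <- function(name) {
  path <- system.file("extdata", name, package = "masldnlp")
  if (!nzchar(path)) stop("bundled config '", name, "' not found", call. = FALSE)
  path
}

# Compile a surface form into a Perl regex: plain strings become whole-word,
# case-insensitive phrase patterns with whitespace/hyphen-flexible gaps;
# "re:"-prefixed strings are taken verbatim.
compile_surface <- function(s) {
  if (startsWith(s, "re:")) return(substring(s, 4L))
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  esc <- gsub("\\s+", "(?:\\\\s|-)+", esc)
  paste0("\\b", esc, "\\b")
}

#' Load a concept lexicon
#'
#' Reads a YAML lexicon mapping concept ids to surface forms and compiles the
#' surface forms into match patterns. The bundled lexicon covers the MASLD
#' histology concepts (steatosis, lobular/portal inflammation, ballooning,
#' steatohepatitis, cirrhosis, fibrosis patterns, nodularity) plus coincident
#' liver diseases (`coincident:*` ids). Users may point `path` at an edited
#' copy; the lexicon is data, not code.
#'
#' @param path YAML file; default: the lexicon bundled with the package.
#' @return data.frame with columns `concept_id`, `surface`, `pattern`.
#' @export
masld_lexicon <- function(path = NULL) {
  if (is.null(path)) path <- config_file("lexicon.yaml")
  raw <- yaml::read_yaml(path)
  entries <- data.frame(
    concept_id = rep(names(raw), lengths(raw)),
    surface = unlist(raw, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(entries$surface))) {
    stop("lexicon contains an empty surface form", call. = FALSE)
  }
  key <- tolower(sub("^re:", "", entries$surface))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    bad <- entries[dup, , drop = FALSE]
    clash <- tapply(bad$concept_id, tolower(sub("^re:", "", bad$surface)),
                    function(x) length(unique(x)) > 1L)
    if (any(clash)) {
      stop("lexicon surface form(s) mapped to two concepts: ",
           paste(names(clash)[clash], collapse = ", "), call. = FALSE)
    }
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  entries$pattern <- vapply(entries$surface, compile_surface, character(1))
  rownames(entries) <- NULL
  entries
}

#' Load negation rules
#'
#' Pre-triggers ("no", "without", ...) negate forward to the nearest scope
#' terminator; post-triggers ("not identified", "is absent", ...) negate
#' backward. Diminutives are listed for documentation and audit only: under
#' the scoring rubric they count as presence and never negate.
#'
#' @param path YAML file; default: bundled rules.
#' @return list with `pre_triggers`, `post_triggers`, `terminators`,
#'   `diminutives`.
#' @export
negation_rules <- function(path = NULL) {
  if (is.null(path)) path <- config_file("negation.yaml")
  rules <- yaml::read_yaml(path)
  needed <- c("pre_triggers", "post_triggers", "terminators")
  miss <- setdiff(needed, names(rules))
  if (length(miss)) stop("negation rules missing: ", paste(miss, collapse = ", "))
  rules
}

#' Load boilerplate section-marker rules
#'
#' @param path YAML file; default: bundled rules.
#' @return list with `diagnosis_markers`, `gross_markers`, `header_markers`,
#'   `footer_markers`.
#' @export
boilerplate_rules <- function(path = NULL) {
  if (is.null(path)) path <- config_file("boilerplate.yaml")
  yaml::read_yaml(path)
}

#' Load biopsy-screening term lists
#'
#' @param path YAML file; default: bundled rules.
#' @return list with `liver_terms`, `non_liver_organs`, `fna_terms`,
#'   `tumor_terms`.
#' @export
screen_rules <- function(path = NULL) {
  if (is.null(path)) path <- config_file("screen.yaml")
  yaml::read_yaml(path)
}

#' Assemble the full pipeline configuration
#'
#' Bundles the lexicon, negation, boilerplate, screening and classification
#' policy configuration consumed by [annotate_report()]. Any component can be
#' replaced to adapt the pipeline to local reporting styles.
#'
#' @param lexicon see [masld_lexicon()].
#' @param negation see [negation_rules()].
#' @param boilerplate see [boilerplate_rules()].
#' @param screen see [screen_rules()].
#' @param policy see [masld_policy()].
#' @return list of class `masld_config`.
#' @export
masld_config <- function(lexicon = masld_lexicon(),
                         negation = negation_rules(),
                         boilerplate = boilerplate_rules(),
                         screen = screen_rules(),
                         policy = masld_policy()) {
  structure(
    list(lexicon = lexicon, negation = negation, boilerplate = boilerplate,
         screen = screen, policy = policy),
    class = "masld_config"
  )
}
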