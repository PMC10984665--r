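#' MASLD report categories and contaminant types
#'
#' Template categories the synthetic generator can realize: the cohort strata
#' (`no_steatosis`, `simple_steatosis`, `mash_f0`..`mash_f3`, `cirrhosis_f4`),
#' the two borderline patterns, and the contaminant report types removed by
#' screening.
#'
#' @return character vector.
#' @export
masld_categories <- function() {
  c("no_steatosis", "simple_steatosis", "mash_f0", "mash_f1", "mash_f2",
    "mash_f3", "cirrhosis_f4", "borderline_ballooning",
    "borderline_inflammation")
}

#' @rdname masld_categories
#' @export
contaminant_types <- function() {
  c("non_liver_organ", "fine_needle_aspiration", "tumor_biopsy")
}

default_category_mix <- function() {
  c(simple_steatosis = 0.18, mash_f0 = 0.12, mash_f1 = 0.12, mash_f2 = 0.10,
    mash_f3 = 0.10, cirrhosis_f4 = 0.10, no_steatosis = 0.08,
    borderline_ballooning = 0.04, borderline_inflammation = 0.06,
    non_liver_organ = 0.05, fine_needle_aspiration = 0.03,
    tumor_biopsy = 0.02)
}

#' Specify a synthetic corpus
#'
#' Defines the composition of a generated pathology-report corpus. The
#' defaults emulate the validation design of the source cohort: 1224 reports,
#' at least 100 gold-positive examples of each of the 9 validated concepts,
#' balanced between pre-2005 descriptive reporting and post-2005 CRN stage
#' notation, with a contaminant admixture (non-liver organs, fine-needle
#' aspirations, tumor biopsies) for the screening step to remove.
#'
#' @param n_reports number of reports.
#' @param category_mix named proportions over [masld_categories()] and
#'   [contaminant_types()]; must sum to 1.
#' @param era_mix named proportions over `pre_2005`/`post_2005`.
#' @param adversarial_rate fraction of liver reports drawn from hard templates
#'   (diminutives, stage ranges, coordinated phrases, negation chains).
#' @param neg_mention_prob probability that a gold-absent feature is realized
#'   as an explicit negation sentence (rather than omitted).
#' @param coincident_rate probability of a coincident-disease sentence.
#' @param min_positives minimum gold-positive count required for each of the
#'   9 validated concepts; generation errors if unmet.
#' @param seed integer; fully determines the corpus.
#' @return list of class `generation_spec`.
#' @export
generation_spec <- function(n_reports = 1224,
                            category_mix = default_category_mix(),
                            era_mix = c(pre_2005 = 0.5, post_2005 = 0.5),
                            adversarial_rate = 0.15,
                            neg_mention_prob = 0.5,
                            coincident_rate = 0.05,
                            min_positives = 100,
                            seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix must sum to 1", call. = FALSE)
  }
  if (abs(sum(era_mix) - 1) > 1e-8) stop("era_mix must sum to 1", call. = FALSE)
  bad <- setdiff(names(category_mix),
                 c(masld_categories(), contaminant_types()))
  if (length(bad)) {
    stop("unknown categories in mix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_reports = as.integer(n_reports), category_mix = category_mix,
         era_mix = era_mix, adversarial_rate = adversarial_rate,
         neg_mention_prob = neg_mention_prob,
         coincident_rate = coincident_rate,
         min_positives = min_positives, seed = as.integer(seed)),
    class = "generation_spec"
  )
}

# largest-remainder apportionment so realized counts match the requested mix
# within integer rounding
apportion <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(mix))
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

# draft the gold feature booleans for a template category; the draft is the
# label, the text realizes it
draft_gold_label <- function(category) {
  d <- list(template = category, steatosis = FALSE,
            lobular_inflammation = FALSE, ballooning = FALSE,
            mash_asserted = FALSE, cirrhosis = FALSE, stage = 0L)
  switch(category,
    no_steatosis = d,
    simple_steatosis = { d$steatosis <- TRUE; d },
    mash_f0 = {
      d$steatosis <- TRUE; d$lobular_inflammation <- TRUE
      d$ballooning <- TRUE; d$mash_asserted <- runif(1) < 0.5; d
    },
    mash_f1 = , mash_f2 = , mash_f3 = {
      d$steatosis <- TRUE; d$lobular_inflammation <- TRUE
      d$ballooning <- runif(1) < 0.5; d$mash_asserted <- runif(1) < 0.5
      d$stage <- as.integer(sub("mash_f", "", category)); d
    },
    cirrhosis_f4 = {
      d$steatosis <- TRUE; d$cirrhosis <- TRUE; d$stage <- 4L
      d$lobular_inflammation <- runif(1) < 0.5
      d$ballooning <- runif(1) < 0.5; d$mash_asserted <- runif(1) < 0.3; d
    },
    borderline_ballooning = { d$steatosis <- TRUE; d$ballooning <- TRUE; d },
    borderline_inflammation = {
      d$steatosis <- TRUE; d$lobular_inflammation <- TRUE; d
    },
    stop("unreachable label category: ", category, call. = FALSE)
  )
}

# derive the classification-consistent gold columns from a draft (gold comes
# from the labels via the truth table, never from re-parsing generated text)
gold_from_draft <- function(d, policy = masld_policy()) {
  features <- structure(
    list(report_id = NA_character_, steatosis = d$steatosis,
         lobular_inflammation = d$lobular_inflammation,
         ballooning = d$ballooning, mash_asserted = d$mash_asserted,
         cirrhosis_asserted = d$cirrhosis, conflict_flags = character(0),
         coincident_diseases = character(0)),
    class = "histology_features"
  )
  fibrosis <- structure(
    list(report_id = NA_character_,
         explicit_stages = parse_explicit_stages(character(0)),
         components = list(perisinusoidal_zone3 = FALSE,
                           zone1_periportal = FALSE, bridging = FALSE,
                           nodularity = FALSE),
         fibrosis_negated = FALSE,
         resolved_stage = paste0("F", d$stage),
         stage_source = "explicit", flags = character(0)),
    class = "fibrosis_assessment"
  )
  classify_report(features, fibrosis, policy)
}

sent_steatosis <- function(adv) {
  if (adv) {
    pick(c("Minimal steatosis.", "Patchy macrovesicular steatosis is noted.",
           "Borderline steatosis, predominantly macrovesicular."))
  } else {
    pick(c("Moderate macrovesicular steatosis.",
           "Marked macrovesicular steatosis involving 60% of hepatocytes.",
           "Mild steatosis is present."))
  }
}

sent_lobular <- function(adv) {
  if (adv) {
    pick(c("Focal lobular inflammation.",
           "Portal and lobular inflammation are present.",
           "Zone 3 inflammation is present."))
  } else {
    pick(c("Mild lobular inflammation is present.",
           "Scattered foci of lobular inflammation.",
           "Lobular inflammation with scattered acidophil bodies."))
  }
}

sent_ballooning <- function(adv) {
  if (adv) {
    pick(c("Rare hepatocyte ballooning.", "Occasional ballooned hepatocytes."))
  } else {
    pick(c("Hepatocyte ballooning is present.",
           "Ballooned hepatocytes are identified.",
           "Ballooning degeneration is noted."))
  }
}

sent_mash <- function(adv) {
  if (adv) {
    "Borderline steatohepatitis."
  } else {
    pick(c("Findings are consistent with steatohepatitis.",
           "Steatohepatitis, grade 2.",
           "Nonalcoholic steatohepatitis."))
  }
}

sent_fibrosis <- function(stage, era, adv) {
  if (era == "post_2005") {
    if (adv && stage >= 1L && stage <= 3L) {
      return(pick(list(
        sprintf("Fibrosis stage F%d-F%d.", stage - 1L, stage),
        sprintf("Fibrosis, stage %d to %d.", stage - 1L, stage),
        if (stage == 3L) "Stage F2 with focal areas of bridging." else
          sprintf("Fibrosis stage F%d-F%d.", stage - 1L, stage)
      )))
    }
    return(switch(as.character(stage),
      "0" = pick(c("Fibrosis stage 0 of 4.", "Stage F0.")),
      "1" = pick(c("Fibrosis stage 1 of 4.", "Stage F1.",
                   "Trichrome stain demonstrates stage 1 fibrosis.")),
      "2" = pick(c("Fibrosis stage 2 of 4.", "Stage F2.",
                   "Trichrome stain demonstrates stage 2 fibrosis.")),
      "3" = pick(c("Fibrosis stage 3 of 4.", "Stage F3.",
                   "Bridging fibrosis, stage 3 of 4.")),
      "4" = "Fibrosis stage 4 of 4."
    ))
  }
  # pre-2005 style: descriptive component prose, no CRN stage vocabulary
  switch(as.character(stage),
    "0" = "No fibrosis is seen.",
    "1" = pick(c("Delicate perisinusoidal fibrosis is present.",
                 "Pericellular fibrosis is noted in zone 3.")),
    "2" = if (adv) {
      "Perisinusoidal and periportal fibrosis are present."
    } else {
      paste("Perisinusoidal fibrosis is present.",
            "Periportal fibrosis is also noted.")
    },
    "3" = pick(c("Bridging fibrosis is present.",
                 "Focal bridging fibrosis is identified.")),
    "4" = "Regenerative nodules with bridging fibrosis."
  )
}

sent_negated <- function(feature) {
  switch(feature,
    steatosis = pick(c("No steatosis is identified.",
                       "Negative for steatosis.")),
    lobular_inflammation = pick(c("No lobular inflammation is seen.",
                                  "Lobular inflammation is not identified.")),
    ballooning = pick(c("No ballooning is seen.",
                        "Ballooning is not identified.")),
    steatohepatitis = "No evidence of steatohepatitis.",
    fibrosis = "No fibrosis is seen."
  )
}

sent_cirrhosis <- function(era) {
  if (era == "post_2005") {
    pick(c("Established cirrhosis with nodular architecture.",
           "Cirrhosis, fibrosis stage 4 of 4."))
  } else {
    pick(c("Established cirrhosis with nodular architecture.",
           "Cirrhotic liver with regenerative nodules."))
  }
}

coincident_sentences <- list(
  hepatitis_c = "The findings are consistent with chronic hepatitis C.",
  granuloma = "Scattered granulomas are present.",
  autoimmune_hepatitis = "Features suggestive of autoimmune hepatitis."
)

random_date <- function(era) {
  rng <- if (era == "pre_2005") {
    c(as.Date("1995-01-01"), as.Date("2004-12-31"))
  } else {
    c(as.Date("2005-01-01"), as.Date("2021-03-01"))
  }
  format(rng[1] + sample.int(as.integer(rng[2] - rng[1]) + 1L, 1L) - 1L)
}

report_header <- function(era, patient_id) {
  clinical <- pick(c("Elevated liver enzymes.",
                     "Abnormal LFTs, rule out steatohepatitis.",
                     "Obesity, diabetes mellitus; evaluate for fatty liver.",
                     "Hepatomegaly of unclear etiology."))
  gross <- pick(c(
    "Received in formalin, a tan-brown core of tissue measuring 1.8 cm.",
    "Two tan needle cores of hepatic tissue, 1.2 and 1.5 cm.",
    "A single yellow-tan core biopsy measuring 2.0 cm, entirely submitted."))
  sprintf(paste0("ACCESSION: S%02d-%05d\nPATIENT: %s\nMRN: %07d\n",
                 "CLINICAL DATA: %s\nGROSS DESCRIPTION: %s\n"),
          sample.int(22L, 1L) - 1L, sample.int(99999L, 1L), patient_id,
          sample.int(9999999L, 1L), clinical, gross)
}

report_footer <- function() {
  pick(c("\nELECTRONICALLY SIGNED BY J. SMITH, M.D.",
         "\nDictated by: A. JONES, M.D.",
         "\nReported by: PATHOLOGY ASSOCIATES\nEnd of report."))
}

diagnosis_heading <- function(era) {
  if (era == "post_2005") {
    pick(c("FINAL PATHOLOGIC DIAGNOSIS:", "DIAGNOSIS:"))
  } else {
    pick(c("DIAGNOSIS:", "MICROSCOPIC DIAGNOSIS:"))
  }
}

contaminant_text <- function(type) {
  switch(type,
    non_liver_organ = pick(c(
      paste("Colon, biopsy: Adenocarcinoma, moderately differentiated.",
            "Liver metastases noted clinically."),
      paste("Stomach, antrum, biopsy: Chronic gastritis.",
            "Hepatic steatosis reported on prior imaging."),
      paste("Breast, left, core biopsy: Invasive ductal carcinoma.",
            "Staging to include liver imaging."))),
    fine_needle_aspiration = pick(c(
      "Liver, fine needle aspiration: Atypical hepatocytes present.",
      "Liver, fine-needle aspiration: Benign hepatocytes and bile duct cells.")),
    tumor_biopsy = pick(c(
      paste("Liver, mass, core biopsy: Metastatic adenocarcinoma,",
            "consistent with colorectal primary."),
      "Liver, biopsy: Hepatocellular carcinoma, moderately differentiated."))
  )
}

#' Generate one synthetic pathology report
#'
#' Realizes a gold label draft as report text: every gold-true feature is
#' expressed by a template sentence (era-styled fibrosis evidence: descriptive
#' component prose pre-2005, CRN stage notation post-2005); gold-false
#' features are expressed as explicit negation sentences with probability
#' `neg_prob`; header/footer boilerplate is attached with recorded section
#' boundaries. Gold labels are drafted first and text second, so gold is
#' independent of the extractor. Uses the ambient RNG; seed upstream for
#' determinism.
#'
#' @param category a [masld_categories()] or [contaminant_types()] entry.
#' @param era `"pre_2005"` or `"post_2005"`.
#' @param adversarial use hard templates (diminutives, ranges, negation
#'   chains, coordinated phrases) where applicable.
#' @param neg_prob probability of realizing a gold-absent core feature as an
#'   explicit negation sentence.
#' @param coincident_rate probability of a coincident-disease sentence.
#' @param report_id,patient_id identifiers.
#' @param draft optional named list overriding the drafted gold feature
#'   booleans/stage (`steatosis`, `lobular_inflammation`, `ballooning`,
#'   `mash_asserted`, `cirrhosis`, `stage`), for exhaustive truth-table
#'   generation. A draft whose derived category contradicts `category` is a
#'   generation error (unreachable label combination).
#' @return list with `report` (report_id, patient_id, report_date, hospital,
#'   text) and `gold` (one-row data.frame of gold labels and section
#'   boundaries).
#' @export
generate_report <- function(category, era = "post_2005", adversarial = FALSE,
                            neg_prob = 0.5, coincident_rate = 0.05,
                            report_id = "SYN-00001",
                            patient_id = "P-00001", draft = NULL) {
  hospital <- pick(c("General Hospital A", "Community Hospital B",
                     "Teaching Hospital C"))
  is_contaminant <- category %in% contaminant_types()

  if (is_contaminant) {
    diag <- contaminant_text(category)
    gold_row <- data.frame(
      report_id = report_id, template = category, contaminant = category,
      era = era, adversarial = adversarial,
      steatosis = NA, lobular_inflammation = NA, ballooning = NA,
      steatohepatitis = NA, cirrhosis = NA, fibrosis_stage = NA_character_,
      category = NA_character_, borderline = NA_character_,
      coincident = "", stringsAsFactors = FALSE
    )
  } else {
    d <- draft_gold_label(category)
    if (!is.null(draft)) d[names(draft)] <- draft
    label <- gold_from_draft(d)
    expected <- if (startsWith(category, "borderline_")) {
      "simple_steatosis"
    } else {
      category
    }
    if (label$category != expected) {
      stop("unreachable label combination: template '", category,
           "' derives category '", label$category, "'", call. = FALSE)
    }
    sents <- character(0)
    if (d$steatosis) sents <- c(sents, sent_steatosis(adversarial))

    chain_ok <- adversarial && d$steatosis && d$lobular_inflammation &&
      !d$ballooning
    if (chain_ok) {
      # negation-chain template: scope of "without" ends at "but"
      sents <- c(sents,
                 "Steatosis without ballooning, but lobular inflammation is present.")
    } else {
      if (d$lobular_inflammation) sents <- c(sents, sent_lobular(adversarial))
      if (d$ballooning) sents <- c(sents, sent_ballooning(adversarial))
      if (!d$ballooning && runif(1) < neg_prob) {
        sents <- c(sents, sent_negated("ballooning"))
      }
      if (!d$lobular_inflammation && runif(1) < neg_prob) {
        sents <- c(sents, sent_negated("lobular_inflammation"))
      }
    }
    if (d$mash_asserted) sents <- c(sents, sent_mash(adversarial))
    if (!d$mash_asserted && d$template %in%
          c("simple_steatosis", "borderline_ballooning",
            "borderline_inflammation") && runif(1) < neg_prob) {
      sents <- c(sents, sent_negated("steatohepatitis"))
    }
    if (!d$steatosis && runif(1) < 0.7) {
      sents <- c(sents, sent_negated("steatosis"))
    }

    if (d$cirrhosis) {
      sents <- c(sents, sent_cirrhosis(era))
    } else if (d$stage > 0L) {
      sents <- c(sents, sent_fibrosis(d$stage, era, adversarial))
    } else if (runif(1) < neg_prob) {
      sents <- c(sents, sent_fibrosis(0L, era, adversarial))
    }

    coincident <- ""
    if (runif(1) < coincident_rate) {
      coincident <- pick(names(coincident_sentences))
      sents <- c(sents, coincident_sentences[[coincident]])
    }
    if (runif(1) < 0.3) {
      sents <- c(sents, "Mild portal chronic inflammation is present.")
    }
    if (runif(1) < 0.3) sents <- c(sents, "No malignancy is identified.")
    if (!length(sents)) sents <- "Unremarkable hepatic parenchyma."

    specimen <- pick(c("Liver, needle core biopsy:", "Liver, biopsy:",
                       "Liver, needle biopsy:"))
    if (runif(1) < 0.3) {
      diag <- paste0(specimen, "\n",
                     paste(sprintf("%d. %s", seq_along(sents), sents),
                           collapse = "\n"))
    } else {
      diag <- paste(specimen, paste(sents, collapse = " "))
    }
    gold_row <- data.frame(
      report_id = report_id, template = category, contaminant = "none",
      era = era, adversarial = adversarial,
      steatosis = d$steatosis || d$mash_asserted,
      lobular_inflammation = d$lobular_inflammation,
      ballooning = d$ballooning,
      steatohepatitis = label$mash, cirrhosis = d$cirrhosis,
      fibrosis_stage = paste0("F", d$stage),
      category = label$category, borderline = label$borderline,
      coincident = coincident, stringsAsFactors = FALSE
    )
  }

  header <- report_header(era, patient_id)
  heading <- diagnosis_heading(era)
  prefix <- paste0(header, heading, " ")
  text <- paste0(prefix, diag, report_footer())
  gold_row$diag_start <- nchar(prefix)            # 0-based
  gold_row$diag_end <- nchar(prefix) + nchar(diag)

  list(
    report = data.frame(report_id = report_id, patient_id = patient_id,
                        report_date = random_date(era), hospital = hospital,
                        text = text, stringsAsFactors = FALSE),
    gold = gold_row
  )
}

#' Generate a labelled synthetic corpus
#'
#' Draws a corpus according to a [generation_spec()]: realized category counts
#' match the requested mix within integer rounding, each of the 9 validated
#' concepts has at least `min_positives` gold-positive reports (generation
#' error otherwise), and the same spec and seed always produce a
#' byte-identical corpus.
#'
#' @param spec a [generation_spec()].
#' @return list of class `masld_corpus` with `reports` (data.frame),
#'   `gold` (data.frame) and `spec`.
#' @export
generate_corpus <- function(spec = generation_spec()) {
  stopifnot(inherits(spec, "generation_spec"))
  withr::with_seed(spec$seed, {
    counts <- apportion(spec$n_reports, spec$category_mix)
    cats <- rep(names(counts), counts)
    cats <- cats[sample.int(length(cats))]
    eras <- rep(names(spec$era_mix),
                apportion(spec$n_reports, spec$era_mix))
    eras <- eras[sample.int(length(eras))]
    out <- lapply(seq_along(cats), function(i) {
      generate_report(
        cats[i], era = eras[i],
        adversarial = runif(1) < spec$adversarial_rate,
        neg_prob = spec$neg_mention_prob,
        coincident_rate = spec$coincident_rate,
        report_id = sprintf("SYN-%05d", i),
        patient_id = sprintf("P-%05d", i)
      )
    })
  })
  reports <- do.call(rbind, lapply(out, `[[`, "report"))
  gold <- do.call(rbind, lapply(out, `[[`, "gold"))
  rownames(reports) <- rownames(gold) <- NULL

  liver <- gold[gold$contaminant == "none", , drop = FALSE]
  pos <- c(
    steatosis = sum(liver$steatosis),
    lobular_inflammation = sum(liver$lobular_inflammation),
    ballooning = sum(liver$ballooning),
    steatohepatitis = sum(liver$steatohepatitis),
    setNames(vapply(paste0("F", 0:4),
                    function(s) sum(liver$fibrosis_stage == s), numeric(1)),
             paste0("F", 0:4))
  )
  low <- pos < spec$min_positives
  if (any(low)) {
    stop("corpus too small for min_positives=", spec$min_positives,
         "; short concepts: ",
         paste(sprintf("%s (%d)", names(pos)[low], pos[low]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(reports = reports, gold = gold, spec = spec),
            class = "masld_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Emits `corpus.jsonl` (one report object per line), `gold.csv`, and
#' `spec.yaml` (the reproducibility record) into `dir`.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "masld_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "corpus.jsonl"), "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$reports))) {
    writeLines(jsonlite::toJSON(as.list(corpus$reports[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  write.csv(corpus$gold, file.path(dir, "gold.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(corpus$spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}
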