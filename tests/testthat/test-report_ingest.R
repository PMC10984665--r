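test_that("a report that is all diagnosis passes through unchanged", {
  txt <- "Liver, biopsy: Moderate steatosis. No ballooning is seen."
  sec <- strip_report_boilerplate(wrap_report(txt))
  expect_identical(sec$diagnostic_text, txt)
  expect_equal(nrow(sec$removed_spans), 0)
  expect_false(sec$no_diagnostic_section)
})

test_that("headers, gross description and footers are stripped with labelled spans", {
  txt <- paste0("ACCESSION: A1\nCLINICAL DATA: Elevated LFTs.\n",
                "GROSS DESCRIPTION: tan core 1.5 cm\n",
                "DIAGNOSIS: Liver, biopsy: steatohepatitis.\n",
                "ELECTRONICALLY SIGNED BY A. B., M.D.")
  sec <- strip_report_boilerplate(wrap_report(txt))
  expect_identical(sec$diagnostic_text, "Liver, biopsy: steatohepatitis.")
  expect_setequal(unique(sec$removed_spans$label), c("header", "gross", "footer"))
  # spans are non-overlapping, 0-based half-open
  sp <- sec$removed_spans[order(sec$removed_spans$start), ]
  expect_true(all(sp$end > sp$start))
  expect_true(all(head(sp$end, -1) <= tail(sp$start, -1)))
  # diagnostic text is the substring at the recorded span
  expect_identical(
    substr(normalize_text(txt), sec$diagnostic_span["start"] + 1,
           sec$diagnostic_span["end"]),
    sec$diagnostic_text
  )
})

test_that("generator-recorded section boundaries match the stripper", {
  set.seed(5)
  for (i in 1:20) {
    g <- generate_report("mash_f1", era = sample(c("pre_2005", "post_2005"), 1),
                         report_id = paste0("B", i))
    sec <- strip_report_boilerplate(g$report)
    expect_equal(unname(sec$diagnostic_span["start"]), g$gold$diag_start)
    expect_equal(unname(sec$diagnostic_span["end"]), g$gold$diag_end)
  }
})

test_that("header-only text with no diagnosis heading is flagged, not dropped", {
  txt <- "ACCESSION: A2\nCLINICAL DATA: rule out NASH.\nGROSS DESCRIPTION: cores"
  sec <- strip_report_boilerplate(wrap_report(txt))
  expect_true(sec$no_diagnostic_section)
  expect_identical(sec$diagnostic_text, "")
})

test_that("stripping is idempotent", {
  set.seed(8)
  for (cat in c("simple_steatosis", "cirrhosis_f4", "non_liver_organ")) {
    g <- generate_report(cat, report_id = cat)
    once <- strip_report_boilerplate(g$report)
    twice <- strip_report_boilerplate(
      wrap_report(once$diagnostic_text, once$report_id))
    expect_identical(twice$diagnostic_text, once$diagnostic_text)
  }
})

test_that("screening keeps parenchymal liver biopsies and excludes contaminants", {
  ok <- strip_report_boilerplate(
    wrap_report("Liver, needle core biopsy: steatosis."))
  s <- screen_parenchymal_biopsy(ok)
  expect_true(s$is_parenchymal_liver_biopsy)
  expect_identical(s$exclusion_reason, "none")

  colon <- strip_report_boilerplate(wrap_report(
    "Colon, biopsy: adenocarcinoma; liver metastases noted clinically."))
  s <- screen_parenchymal_biopsy(colon)
  expect_false(s$is_parenchymal_liver_biopsy)
  expect_identical(s$exclusion_reason, "non_liver_organ")

  fna <- strip_report_boilerplate(wrap_report(
    "Liver, fine needle aspiration: atypical cells."))
  expect_identical(screen_parenchymal_biopsy(fna)$exclusion_reason,
                   "fine_needle_aspiration")

  tumor <- strip_report_boilerplate(wrap_report(
    "Liver, biopsy: Hepatocellular carcinoma, moderately differentiated."))
  expect_identical(screen_parenchymal_biopsy(tumor)$exclusion_reason,
                   "tumor_biopsy")

  none <- strip_report_boilerplate(wrap_report(
    "Skin, punch biopsy: basal cell carcinoma."))
  expect_identical(screen_parenchymal_biopsy(none)$exclusion_reason,
                   "no_liver_mention")
})

test_that("negated tumor language does not exclude a liver biopsy", {
  sec <- strip_report_boilerplate(wrap_report(
    "Liver, biopsy: Steatosis. No hepatocellular carcinoma is identified."))
  expect_true(screen_parenchymal_biopsy(sec)$is_parenchymal_liver_biopsy)
})

test_that("screening precedence is organ > tumor > FNA", {
  sec <- strip_report_boilerplate(wrap_report(
    "Colon, fine needle aspiration: metastatic adenocarcinoma of the liver."))
  expect_identical(screen_parenchymal_biopsy(sec)$exclusion_reason,
                   "non_liver_organ")
  sec2 <- strip_report_boilerplate(wrap_report(
    "Liver, fine needle aspiration: metastatic adenocarcinoma."))
  expect_identical(screen_parenchymal_biopsy(sec2)$exclusion_reason,
                   "tumor_biopsy")
})

test_that("stripping and screening are deterministic across runs", {
  g <- generate_report("mash_f3", report_id = "D1")
  a <- strip_report_boilerplate(g$report)
  b <- strip_report_boilerplate(g$report)
  expect_identical(a, b)
  expect_identical(screen_parenchymal_biopsy(a), screen_parenchymal_biopsy(b))
})

test_that("survivors of screening equal the generator's liver-template count", {
  cc <- generate_corpus(small_corpus_spec(seed = 77, n = 120))
  pred <- annotate_corpus(cc$reports)
  expect_equal(sum(pred$screened_in), sum(cc$gold$contaminant == "none"))
  excl <- pred$exclusion_reason[!pred$screened_in]
  gold_excl <- cc$gold$contaminant[cc$gold$contaminant != "none"]
  expect_equal(sort(excl), sort(gold_excl))
})

test_that("corpus IO round-trips through JSONL and CSV", {
  cc <- generate_corpus(small_corpus_spec(seed = 9, n = 60))
  dir <- withr::local_tempdir()
  write_corpus(cc, dir)
  back <- read_reports(file.path(dir, "corpus.jsonl"))
  expect_equal(back$report_id, cc$reports$report_id)
  expect_equal(back$text, cc$reports$text)
  csv <- file.path(dir, "r.csv")
  utils::write.csv(cc$reports, csv, row.names = FALSE)
  back2 <- read_reports(csv)
  expect_equal(back2$text, cc$reports$text)
})

test_that("malformed corpora are rejected", {
  expect_error(validate_reports(data.frame(report_id = c("a", "a"),
                                           text = c("x", "y"))),
               "duplicate")
  expect_error(validate_reports(data.frame(report_id = "a", text = "")),
               "non-empty")
})
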