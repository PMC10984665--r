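test_that("sentence segmentation handles terminators, list numbering, and bare text", {
  s <- segment_sentences("Steatosis. No ballooning.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("Steatosis.", "No ballooning."))

  s <- segment_sentences("1. Steatohepatitis, stage 2.\n2. No malignancy.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("1. Steatohepatitis, stage 2.", "2. No malignancy."))

  s <- segment_sentences("single sentence without terminal punctuation")
  expect_equal(nrow(s), 1)

  # spans are ordered, non-overlapping, 0-based, and index the source exactly
  txt <- "Mild steatosis is seen.\nNo fibrosis. Stage F0."
  s <- segment_sentences(txt)
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$end > s$start))
  for (i in seq_len(nrow(s))) {
    expect_identical(substr(txt, s$start[i] + 1, s$end[i]), s$text[i])
  }
})

test_that("lexicon matching is longest-match-wins with one concept per span", {
  lex <- masld_lexicon()
  ex <- extract_mentions("Marked macrovesicular steatosis.", lex)
  expect_equal(ex$mentions$concept_id, "steatosis")

  ex <- extract_mentions("Steatohepatitis is present.", lex)
  expect_equal(ex$mentions$concept_id, "steatohepatitis")

  ex <- extract_mentions("Portal and lobular inflammation are present.", lex)
  expect_setequal(ex$mentions$concept_id,
                  c("portal_inflammation", "lobular_inflammation"))

  # "primary biliary cirrhosis" is a coincident disease, not cirrhosis
  ex <- extract_mentions("Consistent with primary biliary cirrhosis.", lex)
  expect_equal(ex$mentions$concept_id, "coincident:pbc")

  # surface_text equals the text at the recorded span
  ex <- extract_mentions("Zone 3 inflammation with hepatocyte ballooning.", lex)
  for (i in seq_len(nrow(ex$mentions))) {
    expect_identical(
      substr(ex$text, ex$mentions$start[i] + 1, ex$mentions$end[i]),
      ex$mentions$surface_text[i]
    )
  }
})

test_that("duplicate surface forms across concepts are a configuration error", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("steatosis:", "  - steatosis", "ballooning:", "  - steatosis"),
             tmp)
  expect_error(masld_lexicon(tmp), "two concepts")
})

test_that("pre- and post-trigger negation scoping sets assertions", {
  ex <- extract_mentions("No ballooning is seen.")
  expect_equal(ex$mentions$assertion, "absent")

  ex <- extract_mentions("Minimal steatosis.")
  expect_equal(ex$mentions$assertion, "present")

  ex <- extract_mentions(
    "Steatosis without ballooning, but lobular inflammation is present.")
  m <- setNames(ex$mentions$assertion, ex$mentions$concept_id)
  expect_equal(m[["steatosis"]], "present")
  expect_equal(m[["ballooning"]], "absent")
  expect_equal(m[["lobular_inflammation"]], "present")

  ex <- extract_mentions("Lobular inflammation is not identified.")
  expect_equal(ex$mentions$assertion, "absent")

  # scope is sentence-bounded: negation in one sentence leaves the next alone
  ex <- extract_mentions("No steatosis. Ballooning is present.")
  m <- setNames(ex$mentions$assertion, ex$mentions$concept_id)
  expect_equal(m[["steatosis"]], "absent")
  expect_equal(m[["ballooning"]], "present")
})

test_that("diminutive qualifiers never negate", {
  for (txt in c("Patchy steatosis.", "Borderline steatohepatitis.",
                "Focal lobular inflammation.", "Rare hepatocyte ballooning.",
                "Early bridging fibrosis.")) {
    ex <- extract_mentions(txt)
    expect_true(all(ex$mentions$assertion == "present"), label = txt)
  }
})

test_that("wrapping a canonical positive sentence in 'No ...' flips only that mention", {
  canon <- c(steatosis = "macrovesicular steatosis",
             lobular_inflammation = "lobular inflammation",
             ballooning = "hepatocyte ballooning",
             steatohepatitis = "steatohepatitis",
             cirrhosis = "cirrhosis")
  for (cc in names(canon)) {
    pos <- extract_mentions(paste0(canon[[cc]], " is present."))
    expect_equal(pos$mentions$assertion[pos$mentions$concept_id == cc],
                 "present", label = cc)
    neg <- extract_mentions(paste0("No ", canon[[cc]], "."))
    expect_equal(neg$mentions$assertion[neg$mentions$concept_id == cc],
                 "absent", label = cc)
  }
  # flipping one sentence leaves mentions in other sentences untouched
  base <- "Steatosis is present. Lobular inflammation is present."
  flip <- "Steatosis is present. No lobular inflammation."
  a <- extract_mentions(base)$mentions
  b <- extract_mentions(flip)$mentions
  expect_equal(a$assertion[a$concept_id == "steatosis"],
               b$assertion[b$concept_id == "steatosis"])
  expect_equal(b$assertion[b$concept_id == "lobular_inflammation"], "absent")
})

test_that("extraction is a pure function of its inputs", {
  set.seed(31)
  g <- generate_report("mash_f2", adversarial = TRUE, report_id = "P1")
  sec <- strip_report_boilerplate(g$report)
  a <- extract_mentions(sec$diagnostic_text)
  b <- extract_mentions(sec$diagnostic_text)
  expect_identical(a, b)
})

test_that("mention-level assertions are perfect on canonical generated reports", {
  set.seed(19)
  cfg <- masld_config()
  n_checked <- 0
  for (cat in masld_categories()) {
    g <- generate_report(cat, era = "post_2005", adversarial = FALSE,
                         report_id = cat)
    ann <- annotate_report(g$report, cfg)
    expect_equal(ann$features$steatosis, g$gold$steatosis, label = cat)
    expect_equal(ann$features$lobular_inflammation,
                 g$gold$lobular_inflammation, label = cat)
    expect_equal(ann$features$ballooning, g$gold$ballooning, label = cat)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, length(masld_categories()))
})
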