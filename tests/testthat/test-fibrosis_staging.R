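test_that("explicit stage patterns are recognized with denominators", {
  s <- parse_explicit_stages("Fibrosis stage 3 of 4.")
  expect_equal(s$stage, 3)
  expect_equal(s$denominator, 4)

  s <- parse_explicit_stages("Stage F1-F2.")
  expect_equal(sort(s$stage), c(1, 2))

  s <- parse_explicit_stages("stage 0")
  expect_equal(s$stage, 0)
  expect_true(is.na(s$denominator))

  s <- parse_explicit_stages("Fibrosis, stage 2 to 3.")
  expect_equal(sort(s$stage), c(2, 3))

  s <- parse_explicit_stages("fibrosis stage III")
  expect_equal(s$stage, 3)

  s <- parse_explicit_stages("stage 3/6")
  expect_equal(s$stage, 3)
  expect_equal(s$denominator, 6)

  s <- parse_explicit_stages("stage 9 fibrosis")
  expect_true(s$malformed)
  expect_true(is.na(s$stage))
})

test_that("component flags come only from present-asserted mentions", {
  ex <- extract_mentions("Perisinusoidal fibrosis is present.")
  comp <- detect_fibrosis_components(ex$mentions)
  expect_true(comp$perisinusoidal_zone3)
  expect_false(comp$bridging)

  ex <- extract_mentions("No bridging fibrosis is seen.")
  comp <- detect_fibrosis_components(ex$mentions)
  expect_false(comp$bridging)

  ex <- extract_mentions("Established cirrhosis with nodular architecture.")
  comp <- detect_fibrosis_components(ex$mentions)
  expect_true(comp$nodularity)

  ex <- extract_mentions("No fibrosis is identified.")
  comp <- detect_fibrosis_components(ex$mentions)
  expect_true(comp$fibrosis_negated)
})

test_that("component mapping reproduces the CRN table on single-pattern inputs", {
  cases <- list(
    list(txt = "Perisinusoidal fibrosis.", stage = "F1"),
    list(txt = "Perisinusoidal fibrosis. Periportal fibrosis.", stage = "F2"),
    list(txt = "Bridging fibrosis.", stage = "F3"),
    list(txt = "Nodule formation.", stage = "F4")
  )
  for (cs in cases) {
    ex <- extract_mentions(cs$txt)
    fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                                 detect_fibrosis_components(ex$mentions))
    expect_equal(fa$resolved_stage, cs$stage, label = cs$txt)
    expect_equal(fa$stage_source, "components", label = cs$txt)
  }
})

test_that("the highest stage wins across ranges, components and explicit stages", {
  ex <- extract_mentions("Fibrosis stage F1-F2.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "F2")
  expect_equal(fa$stage_source, "explicit")

  ex <- extract_mentions("Stage F2 with focal areas of bridging.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "F3")
  expect_equal(fa$stage_source, "components")
})

test_that("omission and negation both resolve to F0 with distinct sources", {
  ex <- extract_mentions("Moderate steatosis only.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "F0")
  expect_equal(fa$stage_source, "omission")

  ex <- extract_mentions("No fibrosis is seen.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "F0")
  expect_equal(fa$stage_source, "negation")
})

test_that("Ishak-scale stages are never remapped; components rescue staging", {
  ex <- extract_mentions("Fibrosis stage 5 of 6.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "unstaged")
  expect_true("scale_mismatch" %in% fa$flags)

  ex <- extract_mentions("Fibrosis stage 5 of 6. Bridging fibrosis is present.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "F3")
  expect_true("scale_mismatch" %in% fa$flags)
})

test_that("cirrhosis assertion forces F4 over lower explicit stages", {
  ex <- extract_mentions("Cirrhosis. Fibrosis stage 2 of 4.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions),
                               cirrhosis_asserted = TRUE)
  expect_equal(fa$resolved_stage, "F4")
})

test_that("zone-1-only fibrosis maps to an audited F1-equivalent", {
  ex <- extract_mentions("Periportal fibrosis is present.")
  fa <- resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                               detect_fibrosis_components(ex$mentions))
  expect_equal(fa$resolved_stage, "F1")
  expect_true("zone1_only" %in% fa$flags)
})

test_that("staging is monotone in added evidence", {
  stage_num <- function(fa) {
    if (fa$resolved_stage == "unstaged") NA_integer_
    else as.integer(sub("F", "", fa$resolved_stage))
  }
  stage_of <- function(txt) {
    ex <- extract_mentions(txt)
    stage_num(resolve_fibrosis_stage(parse_explicit_stages(ex$sentences),
                                     detect_fibrosis_components(ex$mentions)))
  }
  base_cases <- c("Stage F1.", "Perisinusoidal fibrosis.", "Stage F2.",
                  "Bridging fibrosis.")
  higher <- c("Bridging fibrosis is present.", "Nodule formation is seen.")
  lower <- c("Perisinusoidal fibrosis is present.", "Stage F1.")
  for (b in base_cases) {
    s0 <- stage_of(b)
    for (h in higher) expect_gte(stage_of(paste(b, h)), s0)
    for (l in lower) expect_gte(s0, 1)  # lower evidence cannot pull below base
    for (l in lower) expect_equal(stage_of(paste(b, l)) >= s0, TRUE,
                                  label = paste(b, "+", l))
  }
})
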