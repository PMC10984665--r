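# shared fixtures and independent oracles, built in code at test time

wrap_report <- function(text, report_id = "T1") {
  list(report_id = report_id, text = text)
}

make_features <- function(steatosis = FALSE, lobular_inflammation = FALSE,
                          ballooning = FALSE, mash_asserted = FALSE,
                          cirrhosis_asserted = FALSE,
                          report_id = "T1") {
  structure(
    list(report_id = report_id, steatosis = steatosis,
         lobular_inflammation = lobular_inflammation, ballooning = ballooning,
         mash_asserted = mash_asserted, cirrhosis_asserted = cirrhosis_asserted,
         conflict_flags = character(0), coincident_diseases = character(0)),
    class = "histology_features"
  )
}

make_fibrosis <- function(stage = "F0", source = "omission",
                          report_id = "T1") {
  structure(
    list(report_id = report_id,
         explicit_stages = parse_explicit_stages(character(0)),
         components = list(perisinusoidal_zone3 = FALSE,
                           zone1_periportal = FALSE, bridging = FALSE,
                           nodularity = FALSE),
         fibrosis_negated = FALSE, resolved_stage = stage,
         stage_source = source, flags = character(0)),
    class = "fibrosis_assessment"
  )
}

no_components <- function() {
  list(perisinusoidal_zone3 = FALSE, zone1_periportal = FALSE,
       bridging = FALSE, nodularity = FALSE, fibrosis_negated = FALSE)
}

# brute-force per-record confusion oracle: a plain loop over reports
oracle_confusion <- function(pred, gold, concept) {
  counts <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (id in pred$report_id) {
    p_row <- pred[pred$report_id == id, ]
    g_row <- gold[gold$report_id == id, ]
    get1 <- function(row) {
      if (concept %in% paste0("F", 0:4)) row$fibrosis_stage == concept
      else isTRUE(row[[concept]])
    }
    p <- get1(p_row); g <- get1(g_row)
    key <- if (p && g) "tp" else if (p && !g) "fp" else if (!p && g) "fn" else "tn"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# brute-force product-limit estimator: explicit risk-set loop
oracle_cuminc <- function(time, event) {
  ut <- sort(unique(time[event]))
  surv <- 1
  out <- data.frame(time = numeric(0), cum_inc = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    surv <- surv * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, cum_inc = 1 - surv))
  }
  out
}

# hand-written category oracle for the classification truth table
# (steatosis TRUE throughout; stage 0-4; the default policy)
truth_table_oracle <- function() {
  grid <- expand.grid(infl = c(FALSE, TRUE), ball = c(FALSE, TRUE),
                      assert = c(FALSE, TRUE), stage = 0:4,
                      KEEP.OUT.ATTRS = FALSE)
  expected <- c(
    # stage 0: infl, ball, assert varying (infl fastest)
    "simple_steatosis", "simple_steatosis", "simple_steatosis", "mash_f0",
    "mash_f0", "mash_f0", "mash_f0", "mash_f0",
    # stage 1
    "simple_steatosis", "mash_f1", "mash_f1", "mash_f1",
    "mash_f1", "mash_f1", "mash_f1", "mash_f1",
    # stage 2
    "simple_steatosis", "mash_f2", "mash_f2", "mash_f2",
    "mash_f2", "mash_f2", "mash_f2", "mash_f2",
    # stage 3
    "simple_steatosis", "mash_f3", "mash_f3", "mash_f3",
    "mash_f3", "mash_f3", "mash_f3", "mash_f3",
    # stage 4: cirrhosis overrides everything
    rep("cirrhosis_f4", 8)
  )
  borderline <- rep("none", 40)
  borderline[2] <- "inflammation_only"   # infl only, stage 0
  borderline[3] <- "ballooning_only"     # ball only, stage 0
  grid$expected <- expected
  grid$borderline <- borderline
  grid
}

small_corpus_spec <- function(seed = 101, n = 400) {
  generation_spec(n_reports = n, min_positives = 0, seed = seed)
}
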