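---
title: "Scoring MASLD histology from pathology free text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring MASLD histology from pathology free text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masldnlp)
```

# The scoring rubric

A liver-biopsy report is reduced to a small set of report-level labels.
Four core MASLD terms are scored present or absent: steatosis, lobular
inflammation, hepatocyte ballooning, and steatohepatitis as a summative
term. The rubric's conventions, all of which this package implements
literally, are:

* **Any assertion counts.** A pathologist's statement of presence *or*
  absence of a concept is scored as such; a concept never mentioned is
  scored **absent** (omission = absent).
* **Diminutives are presence.** "Minimal", "patchy", "borderline", "mild",
  "focal" and similar qualifiers soften but do not negate: "minimal
  steatosis" is steatosis-present, and a "borderline steatohepatitis"
  assertion sets the MASH-asserted flag (overridable via
  `masld_policy(borderline_mash_counts=)`).
* **Portal is not lobular.** Portal/interface inflammation never counts as
  lobular inflammation; lobular, centrilobular, or zone-3 inflammation
  does. In the bundled lexicon zone-3 phrasings are surface forms *of* the
  lobular-inflammation concept, so the rule holds by construction.
* **Conflicts resolve to present.** If one sentence negates a concept and
  another asserts it (common when findings negate and the impression
  affirms focally), the report-level feature is present and a conflict
  flag is kept for audit.

# Pipeline

## Boilerplate stripping and screening

Reports arrive as free text with accession headers, clinical context,
gross specimen descriptions and signature footers around the diagnostic
text. Section detection is driven by configurable heading-marker lists
(`boilerplate.yaml`) parsed in order of appearance — heading styles vary by
hospital and era, so markers are data, not code. The diagnostic text is
everything after the first diagnosis heading and before the first footer
marker. Reports with header material but no recognizable diagnosis heading
are flagged (`no_diagnostic_section`), never silently dropped. Text is
NFKC-normalized first and every span the package emits is a 0-based
half-open character interval into that normalized text, so offsets are
reproducible across report dialects. Stripping is idempotent.

Screening then keeps bona fide parenchymal liver biopsies. A report is
excluded when it names a non-liver specimen organ ("Colon, biopsy: …"),
is a fine-needle aspiration, or is a biopsy of a hepatic tumor; a section
with no liver/hepatic mention at all is excluded outright. When several
cues fire, the fixed precedence is organ > tumor > FNA — the specimen organ
is the strongest signal, and a fixed order keeps the decision
deterministic. Tumor matching runs through the same negation machinery as
concept extraction, so "No malignancy identified", a routine line in benign
biopsies, never excludes a report.

## Concept extraction and negation

Concept recognition is lexicon-driven. The original pipeline this package
re-implements used a licensed medical-dictionary recognizer; since that
resource cannot be redistributed, the package bundles a curated,
user-editable lexicon (`lexicon.yaml`) of surface forms for each histology
concept, and every entry point accepts a replacement lexicon. Matching is
case-insensitive, word-bounded, whitespace/hyphen-flexible, and
longest-match-wins among overlapping candidates — "steatohepatitis" is one
steatohepatitis mention, not also steatosis; "primary biliary cirrhosis"
is a coincident-disease mention, not cirrhosis. Coordinated phrases
("portal and lobular inflammation") are handled by zero-width lookahead
entries so each conjunct gets its own mention.

Assertions use trigger-based negation scoping, sentence-bounded:
pre-triggers ("no", "without", "negative for", "absence of") negate forward
to the nearest scope terminator ("but", "however", ";", "."), post-triggers
("not identified", "is absent", "not seen") negate backward. So in
"Steatosis without ballooning, but lobular inflammation is present", only
ballooning is absent. Double negation is not resolved (scored absent):
trigger-style rules are auditable precisely because they do not attempt
discourse reasoning. Sentence segmentation respects the numbered diagnosis
lines ("1. …", "2. …") ubiquitous in pathology reports.

## Fibrosis staging

Staging follows the MASH CRN system: F1 perisinusoidal/pericellular
zone-3 fibrosis, F2 zone-3 plus zone-1 (periportal) fibrosis, F3 bridging,
F4 nodule formation/cirrhosis. The resolver first collects explicit
pathologist stage statements — "stage N", "stage N of M", "N/M", "F N",
and ranges ("F1-F2", "2 to 3"), Arabic or Roman — then component evidence,
and takes the **highest** stage across all of it: "F1-F2" becomes F2, and
"F2 with focal areas of bridging" becomes F3. Qualified components
("early bridging") still count — diminutives are presence. A cirrhosis
assertion always forces F4, even against a lower explicit stage.

Two corners were genuinely open and are resolved as explicit, audited
choices:

* **Ishak-style "of 6" stages are never silently remapped** to the CRN
  scale. No published crosswalk governs the pipeline this package
  re-implements, and a wrong mapping would corrupt the endpoint
  definition, so an "of 6" stage with no other evidence yields `unstaged`
  plus a `scale_mismatch` flag; component evidence, when present, rescues
  staging.
* **Zone-1-only fibrosis maps to an F1-equivalent candidate** (the CRN 1c
  analog), flagged `zone1_only`. F2 requires both zones; promoting
  periportal-only fibrosis to F2 would overstage.

With no evidence at all the stage is F0 — from `negation` when fibrosis
was explicitly negated, otherwise from `omission`.

## Report-level classification

Given steatosis, MASH is positive when (a) the pathologist asserted
steatohepatitis, (b) all three elements are present, or (c) the
*stage-supersedes rule*: fibrosis staged F1–F3 plus at least one of
lobular inflammation, ballooning, or an assertion — so steatosis + lobular
inflammation + F2 is MASH/F2 despite absent ballooning. F4 yields
`cirrhosis_f4` regardless of the MASH elements. The supersede rule's exact
scope was ambiguous in its source: whether steatosis + F1–F3 fibrosis with
*zero* MASH co-features should be promoted is not stated. The package's
default does **not** promote (bland fibrotic steatosis stays
`simple_steatosis` with a `fibrosis_without_mash_features` audit note),
because the canonical worked example includes lobular inflammation and
silent promotion would contradict the all-three-elements fallback; the
opposite behaviour sits behind `masld_policy(promote_bland_fibrosis = TRUE)`.

A steatohepatitis assertion implies steatosis (with an audit note): the
summative diagnosis subsumes its defining feature, and without this rule a
report reading only "Steatohepatitis." would classify as `no_steatosis`.

Steatotic non-MASH reports with exactly one co-feature are *borderline*:
`ballooning_only` or `inflammation_only`. In the primary cohort analysis
borderline reports are excluded and flagged; in the sensitivity analysis
ballooning-only becomes MASH/F0 and inflammation-only simple steatosis
(`apply_borderline_policy()`). MASH with unstageable fibrosis defaults to
MASH/F0 (omission = absent), audited.

# Validation metrics

`performance_table()` scores predictions against gold labels per concept —
the four features, cirrhosis, and each fibrosis stage one-vs-rest — as
sensitivity, specificity, PPV, NPV, F1 and support. F1 is the harmonic
mean of precision and recall. Support is implemented as the count of
gold-positive reports (`tp + fn`): of the two circulating definitions
("count of true positives" vs "actual number of occurrences"), the latter
matches standard usage and is independent of classifier quality; they
coincide only for a perfect classifier. Undefined ratios are reported as
`NA`, never 0. Metrics are kept at full precision; display rounding to one
decimal is a formatting step (`format_performance()`). When F1 is
recomputed from a table's *displayed* (rounded) precision and recall, most
rows agree with the displayed F1 to one decimal and the rest to within
0.1 — the residue of upstream full-precision rounding.

# The synthetic corpus

Real pathology corpora are PHI-restricted, so benchmarking uses a
generator whose **gold labels are drafted first and text second** — gold is
derived from the label via the classification truth table, never by
re-parsing generated text, which keeps validation non-circular. Defaults
mirror the validation design of the study this package re-implements:
1224 reports, at least 100 gold-positive examples of each of the nine
validated concepts, an even split between two reporting eras. Pre-2005
templates avoid stage vocabulary and describe fibrosis components in
prose; post-2005 templates use CRN stage notation — mirroring how
reporting changed after the CRN rubric was established in 2005. Each
report carries era-styled header/footer boilerplate with recorded section
boundaries, an adversarial fraction (default 0.15) uses hard templates
(diminutives, stage ranges, coordinated phrases, negation chains), absent
features are realized as explicit negation sentences with probability 0.5,
and contaminant templates (non-liver organs, FNAs, tumor biopsies; 10% of
the default mix) exercise the screening step.

What passing tests on this corpus shows: the extraction, staging and
classification rules are internally sound — every reachable label
round-trips exactly, negation flips exactly the targeted concept, and the
screen removes exactly the contaminants. What it does **not** show:
performance on real reports, whose stylistic variance (dozens of
pathologists over three decades) exceeds any template family. The
generator makes no attempt at statistical mimicry of real report length or
vocabulary; perfect scores here are a soundness check, not an accuracy
claim.

# Incidence arithmetic

Rates are `1000 * events / person_years`. Confidence intervals are exact
Poisson (Garwood, chi-square) by default: `qchisq(alpha/2, 2x)/2` to
`qchisq(1-alpha/2, 2(x+1))/2`, scaled by person-time, lower bound 0 at
zero events. The published tables this module reproduces label their
intervals "normal approximation", but their printed bounds are
reproduced — to the printed precision — by the exact Poisson formula and
not by the normal approximation, so exact is the default and
`method = "normal"` is available behind a flag. Absolute rate differences
use the normal approximation on unrounded rates:
`diff ± z · 1000 · sqrt(e_a/py_a² + e_b/py_b²)`. Cumulative incidence is
the product-limit estimate (1 − Kaplan–Meier survival) via
`survival::survfit()`, and a 30-day landmark filter supports the
early-event sensitivity analysis. Multivariable Cox modelling is out of
scope; `incidence_table()` exposes the survival-ready layout instead.

`simulate_masld_cohort()` draws exponential event times at per-category
hazards with uniform administrative censoring over 30 years of potential
follow-up (a span matching a multi-decade biopsy cohort), 1000 patients
per group by default. At the default hazards (15, 15, 19, 31, 86 per 1000
person-years for steatosis, F0, F1, F2, F3) each group accrues roughly
10,000–13,000 person-years, giving a Monte-Carlo coefficient of variation
near 7% for the lowest-hazard groups — hence the seed-pinned 15%
relative-error check in the acceptance suite.

# Numerical and engineering choices

* Spans: 0-based half-open, over NFKC-normalized text; all matching
  case-insensitive. Deterministic tie-breaks everywhere (longest match,
  then earliest start, then lexicon order; fixed screening precedence).
* Configuration is data: lexicon, negation triggers, boilerplate markers
  and screening terms are YAML files; every function accepts replacements.
* The generator is driven entirely by one seed via `withr::with_seed()`;
  the same spec and seed produce byte-identical corpora.
* Problem sizes in the test-suite: corpora of 60–400 reports for module
  tests, the full 1224-report default for the generator's
  minimum-positives contract, an 82-report exhaustive truth-table corpus
  for round-trip soundness, and 5×1000 patients for hazard recovery —
  sizes chosen to exercise every rule while keeping the suite quick to
  run routinely.

# Known limitations

* The bundled lexicon is a curated reconstruction, not the (unpublishable)
  original dictionary-driven recognizer; real-world deployment should
  expect lexicon tuning per site. The recognizer boundary is a plain
  data.frame of patterns, so an external engine can be substituted.
* Negation handling does not model uncertainty/hedging ("cannot exclude
  steatohepatitis" scores present) or cross-sentence anaphora.
* Steatosis grade, NAS/SAF composite scores, and addendum/amendment
  threading are out of scope.
* Coincident-disease detection is report-text-only; medication, ICD and
  serology-based exclusions require external data.
* Cumulative-incidence estimates ignore competing risks (death,
  transplantation), so absolute risks are, if anything, overestimated.
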