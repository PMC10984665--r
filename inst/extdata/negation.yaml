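# Trigger-based negation rules. A mention is scored absent when it lies inside
# the scope of a trigger in its own sentence: forward from a pre-trigger (or
# backward from a post-trigger) to the nearest scope terminator. Diminutive
# qualifiers never negate; under the scoring rubric they count as presence.
pre_triggers:
  - "no"
  - without
  - negative for
  - absence of
  - no evidence of
  - no evidence for
  - free of
  - lacking
post_triggers:
  - not identified
  - not seen
  - not present
  - not observed
  - not appreciated
  - not noted
  - is absent
  - are absent
  - absent
terminators:
  - but
  - however
  - whereas
  - although
  - ";"
  - "."
diminutives:
  - minimal
  - patchy
  - borderline
  - mild
  - focal
  - rare
  - occasional
  - early
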