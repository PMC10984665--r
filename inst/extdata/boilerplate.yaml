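# Section heading markers used to strip non-diagnostic boilerplate. Markers
# are matched case-insensitively as "MARKER:". Heading styles vary by hospital
# and era, so these lists are data, not code, and can be overridden.
diagnosis_markers:
  - final pathologic diagnosis
  - final pathological diagnosis
  - pathologic diagnosis
  - final diagnosis
  - diagnosis
  - findings and impression
  - impression
  - microscopic diagnosis
gross_markers:
  - gross description
  - gross examination
  - gross
  - specimen description
header_markers:
  - accession
  - accession number
  - patient
  - patient name
  - mrn
  - medical record number
  - dob
  - date of birth
  - clinical data
  - clinical history
  - clinical information
  - clinical context
  - specimen received
  - specimen
  - date of procedure
  - date of service
  - requisition
footer_markers:
  - electronically signed
  - electronically signed by
  - dictated by
  - reported by
  - reviewed by
  - attending pathologist
  - end of report
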