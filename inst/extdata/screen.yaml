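# Screening term lists for identifying bona fide parenchymal liver biopsies.
# Reports naming a non-liver specimen organ, fine-needle aspirations, and
# biopsies of hepatic tumors are excluded. Tumor terms are assertion-aware
# ("no malignancy" does not exclude).
liver_terms:
  - liver
  - hepatic
non_liver_organs:
  - colon
  - rectum
  - small bowel
  - duodenum
  - stomach
  - esophagus
  - pancreas
  - gallbladder
  - kidney
  - lung
  - breast
  - skin
  - prostate
  - bladder
  - ovary
  - uterus
  - cervix
  - thyroid
  - appendix
  - bone marrow
  - lymph node
fna_terms:
  - fine needle aspiration
  - fine-needle aspiration
  - fine needle aspirate
  - fna
tumor_terms:
  - hepatocellular carcinoma
  - cholangiocarcinoma
  - metastatic carcinoma
  - metastatic adenocarcinoma
  - metastatic
  - hepatic tumor
  - liver mass
  - mass lesion
  - hepatoblastoma
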