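# Curated histology concept lexicon. Plain strings are matched as
# case-insensitive whole-word phrases (spaces match any whitespace/hyphen run);
# entries prefixed "re:" are raw Perl regular expressions. No surface form may
# appear under two concepts.
steatosis:
  - steatosis
  - steatotic change
  - fatty change
  - fatty liver
  - fatty metamorphosis
  - fat accumulation
  - lipid droplet accumulation
lobular_inflammation:
  - lobular inflammation
  - lobular chronic inflammation
  - lobular inflammatory infiltrate
  - lobular mixed inflammation
  - intralobular inflammation
  - lobular activity
  - lobular hepatitis
  - lobulitis
  - zone 3 inflammation
  - zone III inflammation
  - centrilobular inflammation
  - spotty lobular necroinflammation
  - "re:\\blobular(?=(?:\\s|-)+and(?:\\s|-)+portal\\s+inflammation\\b)"
portal_inflammation:
  - portal inflammation
  - portal chronic inflammation
  - portal tract inflammation
  - portal lymphocytic infiltrate
  - portal inflammatory infiltrate
  - interface hepatitis
  - interface activity
  - periportal inflammation
  - "re:\\bportal(?=(?:\\s|-)+and(?:\\s|-)+lobular\\s+inflammation\\b)"
ballooning:
  - ballooning
  - hepatocyte ballooning
  - ballooning degeneration
  - ballooned hepatocytes
  - balloon cell change
  - balloon cells
  - hepatocellular ballooning
steatohepatitis:
  - steatohepatitis
  - nonalcoholic steatohepatitis
  - non-alcoholic steatohepatitis
  - NASH
  - steatohepatitic pattern
cirrhosis:
  - cirrhosis
  - cirrhotic liver
  - micronodular cirrhosis
  - macronodular cirrhosis
  - established cirrhosis
fibrosis_generic:
  - fibrosis
  - fibrotic change
  - hepatic fibrosis
perisinusoidal_fibrosis:
  - perisinusoidal fibrosis
  - pericellular fibrosis
  - perisinusoidal/pericellular fibrosis
  - pericellular/perisinusoidal fibrosis
  - zone 3 fibrosis
  - zone III fibrosis
  - sinusoidal fibrosis
  - chicken-wire fibrosis
  - "re:\\bperisinusoidal(?=(?:\\s|-)+and(?:\\s|-)+periportal\\s+fibrosis\\b)"
  - "re:\\bpericellular(?=(?:\\s|-)+and(?:\\s|-)+periportal\\s+fibrosis\\b)"
periportal_fibrosis:
  - periportal fibrosis
  - zone 1 fibrosis
  - zone I fibrosis
  - portal fibrosis
  - portal/periportal fibrosis
  - periportal fibrous expansion
  - portal fibrous expansion
  - "re:\\bperiportal(?=(?:\\s|-)+and(?:\\s|-)+perisinusoidal\\s+fibrosis\\b)"
bridging_fibrosis:
  - bridging fibrosis
  - bridging
  - fibrous septa
  - fibrous bridging
  - portal-central bridging
  - portal-portal bridging
  - septal fibrosis
nodularity:
  - nodular architecture
  - nodule formation
  - regenerative nodules
  - parenchymal nodularity
  - nodularity
"coincident:hepatitis_c":
  - hepatitis C
  - chronic hepatitis C
  - HCV infection
  - HCV
"coincident:hepatitis_b":
  - hepatitis B
  - chronic hepatitis B
  - HBV infection
  - HBV
"coincident:autoimmune_hepatitis":
  - autoimmune hepatitis
"coincident:pbc":
  - primary biliary cholangitis
  - primary biliary cirrhosis
"coincident:psc":
  - primary sclerosing cholangitis
  - sclerosing cholangitis
"coincident:iron_overload":
  - hemochromatosis
  - iron overload
  - hemosiderosis
"coincident:granuloma":
  - granuloma
  - granulomas
  - granulomatous inflammation
"coincident:alpha1_antitrypsin":
  - alpha-1 antitrypsin deficiency
  - alpha 1 antitrypsin globules
"coincident:wilson_disease":
  - Wilson disease
  - Wilson's disease
"coincident:alcoholic_hepatitis":
  - alcoholic hepatitis
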