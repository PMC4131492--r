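cui	preferred_name	semantic_types	surface_forms
C1705187	Safety	Qualitative Concept	safety
C0002915	General Anesthesia	Therapeutic or Preventive Procedure	general anesthesia
C0278134	Anaesthesia	Therapeutic or Preventive Procedure	anesthesia
C1623040	Breastfeeding (mother)	Finding	breast feeding
C0006147	Breast Feeding	Organism Function	breastfeeding
C0004096	Asthma	Disease or Syndrome	asthma
C0013227	Pharmaceutical Preparations	Pharmacologic Substance	medications|medication
C0032961	Pregnancy	Organism Function	pregnancy
C0549206	Patient currently pregnant	Finding	pregnant
C0019112	Hemorrhoids	Disease or Syndrome	hemorrhoids
C0000737	Abdominal Pain	Sign or Symptom	abdominal pain
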