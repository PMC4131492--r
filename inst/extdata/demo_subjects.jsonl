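{"id":"Safety of general anesthesia","subject":"Safety of general anesthesia","body":"","topic":null}
{"id":"Breast feeding and asthma medications","subject":"Breast feeding and asthma medications","body":"","topic":null}
{"id":"Asthma and pregnancy","subject":"Asthma and pregnancy","body":"","topic":null}
{"id":"Hemorrhoids accompanied by abdominal pain","subject":"Hemorrhoids accompanied by abdominal pain","body":"","topic":null}
{"id":"Breastfeeding and getting pregnant","subject":"Breastfeeding and getting pregnant","body":"","topic":null}
{"id":"Pregnancy while on TB Medications","subject":"Pregnancy while on TB Medications","body":"","topic":null}
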