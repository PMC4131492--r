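topic	key_cuis	cui_set
Anesthesia	C0278134|C0002915|C0002903	C0278134|C0002915|C0002903
Asthma	C0004096|C2984299	C0004096|C2984299
Breast Feeding	C0006147|C1623040	C0006147|C1623040
Pain Management	C0002766|C0030193	C0002766|C0030193|C0000737
Pharmacy and Medications	C0031322|C0013227|C0802604	C0031322|C0013227|C0802604
Pregnancy	C0032961|C0553641|C0549206	C0032961|C0553641|C0549206|C0585066|C0041747|C0232989|C0404831|C0032995|C1291689|C0242786|C0425984|C0425983|C0425986|C0425985|C0149973|C0425987|C0232993|C0232992|C0232990|C0404842|C2586154
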