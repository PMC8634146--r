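word	pronunciation	lemma	case	number	frequency	gender
Aal	al	Aal	Nominative	Singular	29	M
Aal	al	Aal	Dative	Singular	29	M
Aal	al	Aal	Accusative	Singular	29	M
Aale	al@	Aal	Nominative	Plural	34	M
Aale	al@	Aal	Genitive	Plural	34	M
Aalen	al@n	Aal	Dative	Plural	17	M
Aalen	al@n	Aal	Accusative	Plural	17	M
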