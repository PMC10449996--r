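site	phenotype	sex	n
SickKids	NDD	male	4862
SickKids	NDD	female	2245
SickKids	CA	male	958
SickKids	CA	female	865
CreditValley	NDD	male	2417
CreditValley	NDD	female	1096
CreditValley	CA	male	763
CreditValley	CA	female	590
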