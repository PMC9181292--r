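source_id	gene
D-lactose	lacZ
D-lactose	lacY
D-lactose	lacA
D-galactose	galE
D-galactose	galT
D-galactose	galK
D-galactose	galM
D-glucose	ptsG
D-glucose	crr
D-glucose	glk
D-fructose	fruA
D-fructose	fruB
D-fructose	fruK
D-trehalose	treB
D-trehalose	treC
Oleic acid	fadL
Oleic acid	fadD
Oleic acid	fadE
D-maltose	malE
D-maltose	malF
D-maltose	malG
D-maltose	malP
D-maltose	malQ
D-maltose	malT
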