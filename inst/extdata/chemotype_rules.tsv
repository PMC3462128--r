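chemotype	chemotype_name	combination	unique
Ang	Angucyclines	ARO_a,ARO_b,CYC_a	yes
Ant	Anthracyclines	ARO_a,ARO_b,CYC_c,CYC_f	yes
Ant	Anthracyclines	ARO_a,ARO_b,CYC_f	yes
Ant	Anthracyclines	ARO_a,ARO_b,CYC_c,CYC_e	no
Ant	Anthracyclines	ARO_a,CYC_c	yes
Ben	Benzoisochromanequinones	ARO_a,ARO_b,CYC_d	yes
Ben	Benzoisochromanequinones	ARO_b,CYC_d	yes
Pen	Pentangular polyphenols	ARO_c,CYC_b	yes
Pen	Pentangular polyphenols	ARO_c,CYC_a,CYC_b	no
Tcm	Tetracenomycins	ARO_c,CYC_a,CYC_b	no
Tet/Aur	Tetracyclines/aureolic acids	ARO_a,ARO_b,CYC_c,CYC_e	no
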