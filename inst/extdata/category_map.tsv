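# Default functional grouping of OST-HTH partner domains:
# RNA-binding partners, "anchoring" protein/lipid-interaction modules,
# and ubiquitin-system domains. Anything unlisted is "other".
domain	category
RRM	RNA-binding
KH	RNA-binding
CCCH	RNA-binding
S1/CSD-OB	RNA-binding
dsRBD	RNA-binding
Zn-knuckle	RNA-binding
Tudor	anchoring
WW	anchoring
Ankyrin	anchoring
MORN	anchoring
SGNH	anchoring
Sfi1	anchoring
RING	Ub-system
U-box	Ub-system
B-Box	Ub-system
Little-finger	Ub-system
Ubl	Ub-system
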