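# Synthetic genotype catalog: gene-content sets formed by pairwise unions of
# the bundled reference haplotypes. IDs '1' (canonical 9-gene AA genotype) and
# '6' (all 16 loci) follow AFND numbering; SYNxx IDs are synthetic stand-ins.
# Replace with an AFND-derived catalog for production genotype naming.
genotype_id,KIR2DL1,KIR2DL2,KIR2DL3,KIR2DL4,KIR2DL5,KIR2DS1,KIR2DS2,KIR2DS3,KIR2DS4,KIR2DS5,KIR3DL1,KIR3DL2,KIR3DL3,KIR3DS1,KIR2DP1,KIR3DP1
SYN01,0,1,0,1,0,0,1,0,1,0,1,1,1,0,0,1
1,1,0,1,1,0,0,0,0,1,0,1,1,1,0,1,1
SYN02,1,0,1,1,0,1,0,0,0,0,0,1,1,1,1,1
SYN03,0,1,0,1,1,1,1,0,0,1,0,1,1,1,0,1
SYN04,1,1,1,1,0,0,1,0,1,0,1,1,1,0,1,1
SYN05,1,0,1,1,1,1,0,0,0,1,0,1,1,1,1,1
SYN06,1,0,1,1,0,1,0,0,1,0,1,1,1,1,1,1
SYN07,1,1,0,1,1,0,1,1,1,0,1,1,1,0,1,1
SYN08,0,1,0,1,1,1,1,0,1,1,1,1,1,1,0,1
SYN09,1,1,1,1,1,1,1,0,0,1,0,1,1,1,1,1
SYN10,1,1,1,1,1,0,1,1,1,0,1,1,1,0,1,1
SYN11,1,1,1,1,0,1,1,0,1,0,1,1,1,1,1,1
SYN12,1,1,0,1,1,1,1,1,0,1,0,1,1,1,1,1
SYN13,1,0,1,1,1,1,0,0,1,1,1,1,1,1,1,1
SYN14,1,1,1,1,1,1,1,1,0,1,0,1,1,1,1,1
SYN15,1,1,1,1,1,1,1,1,1,0,1,1,1,1,1,1
SYN16,1,1,1,1,1,1,1,0,1,1,1,1,1,1,1,1
SYN17,1,1,0,1,1,1,1,1,1,1,1,1,1,1,1,1
6,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
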