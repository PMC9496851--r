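# Reference KIR gene-content haplotypes (cen~tel motifs, Vierra-Green nomenclature).
# Motif contents: cA01 = 3DL3,2DL3,2DP1,2DL1,3DP1; cB01 = 3DL3,2DS2,2DL2,2DL5,2DS3,2DP1,2DL1,3DP1;
# cB02 = 3DL3,2DS2,2DL2,3DP1; tA01 = 2DL4,3DL1,2DS4,3DL2; tB01 = 2DL4,3DS1,2DL5,2DS5,2DS1,3DL2;
# tB05 = 2DL4,3DS1,2DS1,3DL2. The 2DS3/2DS5 locus is duplicated across cen/tel motifs; haplotypes
# are matched on total gene content, motif placement is metadata. File is user-replaceable.
name,cen_motif,tel_motif,KIR2DL1,KIR2DL2,KIR2DL3,KIR2DL4,KIR2DL5,KIR2DS1,KIR2DS2,KIR2DS3,KIR2DS4,KIR2DS5,KIR3DL1,KIR3DL2,KIR3DL3,KIR3DS1,KIR2DP1,KIR3DP1
cA01~tA01,cA01,tA01,1,0,1,1,0,0,0,0,1,0,1,1,1,0,1,1
cA01~tB01 2DS5,cA01,tB01,1,0,1,1,1,1,0,0,0,1,0,1,1,1,1,1
cB02~tB01,cB02,tB01,0,1,0,1,1,1,1,0,0,1,0,1,1,1,0,1
cB02~tA01,cB02,tA01,0,1,0,1,0,0,1,0,1,0,1,1,1,0,0,1
cA01~tB05,cA01,tB05,1,0,1,1,0,1,0,0,0,0,0,1,1,1,1,1
cB01~tA01 2DS3,cB01,tA01,1,1,0,1,1,0,1,1,1,0,1,1,1,0,1,1
cB01~tB01 2DS3,cB01,tB01,1,1,0,1,1,1,1,1,0,1,0,1,1,1,1,1
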