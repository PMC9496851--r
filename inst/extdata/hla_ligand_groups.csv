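# HLA allele-group -> KIR ligand epitope lookup (two-digit resolution).
# C1/C2: asparagine vs lysine at HLA-C position 80. Bw4: HLA-B Bw4 groups plus
# A*23/A*24/A*32; Bw4_80I: isoleucine-80 subset, restricted to B-locus groups
# (the KIR3DS1-ligand convention). Groups mixing epitopes across alleles are
# assigned the majority-allele epitope; table is user-replaceable and should be
# reviewed for populations with unusual allele composition.
allele_group,epitopes
A*01,
A*02,
A*03,A3
A*11,A11
A*23,Bw4
A*24,Bw4
A*25,
A*26,
A*29,
A*30,
A*31,
A*32,Bw4
A*33,
A*68,
B*07,
B*08,
B*13,Bw4
B*14,
B*15,
B*18,
B*27,Bw4
B*35,
B*37,Bw4
B*38,Bw4;Bw4_80I
B*39,
B*40,
B*41,
B*42,
B*44,Bw4
B*45,
B*46,
B*47,Bw4
B*48,
B*49,Bw4;Bw4_80I
B*50,
B*51,Bw4;Bw4_80I
B*52,Bw4;Bw4_80I
B*53,Bw4;Bw4_80I
B*55,
B*56,
B*57,Bw4;Bw4_80I
B*58,Bw4;Bw4_80I
B*59,Bw4
B*60,
B*61,
B*62,
C*01,C1
C*02,C2
C*03,C1
C*04,C2
C*05,C2
C*06,C2
C*07,C1
C*08,C1
C*12,C1
C*14,C1
C*15,C2
C*16,C1;C16
C*17,C2
C*18,C2
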