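# Population x gene KIR carrier-frequency table (fractions).
# 'Medellin' row: study carrier frequencies; all other populations are
# SYNTHETIC archetypes for exercising the comparison machinery and do not
# correspond to any real published population.
population,n,region,KIR2DL1,KIR2DL2,KIR2DL3,KIR2DL4,KIR2DL5,KIR2DS1,KIR2DS2,KIR2DS3,KIR2DS4,KIR2DS5,KIR3DL1,KIR3DL2,KIR3DL3,KIR3DS1,KIR2DP1,KIR3DP1
Medellin,161,study,0.95,0.54,0.888,1,0.689,0.596,0.534,0.199,0.932,0.571,0.938,1,1,0.714,0.95,1
SynthAsiaA,159,synthetic,0.989,0.258,0.966,1,0.35,0.287,0.265,0.206,0.94,0.3,0.951,1,1,0.307,0.967,1
SynthEuroAB,485,synthetic,0.962,0.532,0.893,1,0.53,0.396,0.561,0.287,0.971,0.332,0.952,1,1,0.419,0.949,1
SynthAfr,366,synthetic,1,0.619,0.915,1,0.5,0.246,0.589,0.345,0.959,0.311,0.972,1,1,0.176,0.928,1
SynthAmerB1,235,synthetic,0.893,0.47,0.793,1,0.714,0.592,0.412,0.087,0.897,0.598,0.898,1,1,0.724,0.939,1
SynthAmerB2,516,synthetic,0.922,0.489,0.857,1,0.603,0.554,0.529,0.131,0.899,0.532,0.928,1,1,0.645,0.937,1
SynthAmerind,666,synthetic,0.857,0.318,0.751,1,0.767,0.663,0.324,0.009,0.808,0.707,0.917,1,1,0.783,0.824,1
SynthIndia,263,synthetic,0.997,0.497,0.852,1,0.673,0.603,0.505,0.224,0.917,0.515,0.935,1,1,0.689,0.979,1
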