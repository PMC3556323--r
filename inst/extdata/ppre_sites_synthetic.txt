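# Synthetic stand-in for a literature-curated list of validated
# DR1-type PPRE site sequences (13 bp, aligned). Constructed, not
# experimental: position 4 is uniform over ACGT, all other columns
# are fixed, so the derived consensus is GGGNCAAAGGTCA.
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGACAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGCCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGGCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
GGGTCAAAGGTCA
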