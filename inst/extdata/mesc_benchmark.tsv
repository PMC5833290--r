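# Binary benchmark ("checkerboard") expression pattern: 12 TFs x 5
# self-renewal-permissive culture conditions. 1 = expressed, 0 = not
# expressed. Reconstruction of the discretized expression data of
# Dunn et al. (2014) for the mESC network; columns are the five signal
# combinations under which mESC self-renewal is observed. Rows for Stat3 and
# MEKERK record pathway activity (LIF-dependent and PD-sensitive,
# respectively). Curated from the primary literature; data, not code.
gene	LIF+2i	2i	LIF+CH	LIF+PD	LIF
Stat3	1	0	1	1	1
MEKERK	0	0	1	0	1
Gbx2	1	0	1	1	1
Klf4	1	0	1	1	1
Klf2	1	1	1	1	1
Tfcp2l1	1	1	1	1	1
Esrrb	1	1	1	0	0
Tbx3	1	1	1	1	0
Sall4	1	1	1	1	1
Nanog	1	1	1	1	1
Sox2	1	1	1	1	1
Oct4	1	1	1	1	1
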