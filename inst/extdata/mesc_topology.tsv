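# mESC naive-pluripotency regulatory network: 12 genes, 3 extracellular
# signals (LIF, CH = GSK3 inhibitor CHIR99021, PD = MEK inhibitor PD0325901).
# Reconstruction of the minimal transcription-factor program inferred by
# Dunn et al. (2014, Science 344:1156) from expression under defined culture
# conditions. Anchored interactions: LIF activates Stat3; PD inhibits
# MEK/ERK; CH feeds into Tfcp2l1; Nanog is regulated by Klf2, Sox2 and
# MEK/ERK; exactly Tfcp2l1, Esrrb, Nanog and Oct4 receive both activating
# and repressing inputs. Edges not fixed by those anchors were curated once
# from the primary mESC literature; this file is data and may be corrected
# without code changes.
#nodes
LIF	signal
CH	signal
PD	signal
Stat3	gene
MEKERK	gene
Gbx2	gene
Klf4	gene
Klf2	gene
Tfcp2l1	gene
Esrrb	gene
Tbx3	gene
Sall4	gene
Nanog	gene
Sox2	gene
Oct4	gene
#edges
LIF	Stat3	activating
CH	Tfcp2l1	activating
PD	MEKERK	repressing
Stat3	Tfcp2l1	activating
Stat3	Gbx2	activating
Stat3	Klf4	activating
Gbx2	Klf4	activating
Oct4	Tfcp2l1	repressing
MEKERK	Esrrb	repressing
MEKERK	Nanog	repressing
Tfcp2l1	Klf2	activating
Klf4	Klf2	activating
Tfcp2l1	Esrrb	activating
Nanog	Esrrb	activating
Klf2	Nanog	activating
Sox2	Nanog	activating
Esrrb	Tbx3	activating
Oct4	Sall4	activating
Esrrb	Oct4	activating
Nanog	Oct4	activating
Sall4	Oct4	activating
Tfcp2l1	Oct4	repressing
Oct4	Sox2	activating
Esrrb	Sox2	activating
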