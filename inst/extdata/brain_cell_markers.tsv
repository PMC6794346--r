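gene	cell_type
S100A9	microglia
CTSD	microglia
CST3	microglia
LTF	microglia
HSPA1A	microglia
CD14	microglia
S100A8	microglia
ITGB2	microglia
HPN	microglia
SPP1	microglia
FCER1G	microglia
MFGE8	astrocyte
SLC39A12	astrocyte
ATP1A2	astrocyte
ALDH1L1	astrocyte
AGT	astrocyte
FXYD1	astrocyte
A2M	astrocyte
ABCD2	astrocyte
CYBRD1	astrocyte
GSN	oligodendrocyte
ENPP6	oligodendrocyte
SLC44A1	oligodendrocyte
CRABP1	neuron
CPNE7	neuron
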