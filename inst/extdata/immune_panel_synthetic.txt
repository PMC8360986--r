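# Synthetic stand-in immune gene panel (73 genes).
# The original study's 73-gene immune panel is not published; this is a
# plausible substitute covering checkpoints, T/B/NK markers, cytokines,
# chemokines and antigen presentation, for examples and simulations.
CD274
PDCD1
PDCD1LG2
CTLA4
LAG3
HAVCR2
TIGIT
IDO1
CD8A
CD8B
CD4
CD3D
CD3E
CD3G
CD2
CD19
MS4A1
NKG7
GZMA
GZMB
GZMK
PRF1
IFNG
TNF
IL2
IL6
IL10
IL12A
IL12B
IL15
CXCL9
CXCL10
CXCL11
CXCL13
CCL2
CCL3
CCL4
CCL5
CCR7
CXCR3
CXCR4
FOXP3
IL2RA
ICOS
CD28
CD40
CD40LG
CD27
CD70
TNFRSF9
TNFRSF4
TNFRSF18
BTLA
VSIR
CD276
VTCN1
HLA-A
HLA-B
HLA-C
HLA-DRA
HLA-DRB1
HLA-DPA1
HLA-DQA1
B2M
TAP1
TAP2
STAT1
IRF1
CD68
CD163
ITGAM
NCAM1
KLRD1
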