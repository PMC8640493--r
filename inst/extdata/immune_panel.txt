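ARG1
B2M
BATF3
CCL2
CCL3
CCL4
CCL5
CCR5
CCR7
CD27
CD274
CD276
CD28
CD3E
CD4
CD40
CD40LG
CD44
CD47
CD68
CD8A
CD8B
CDK1
CSF1R
CTLA4
CXCL10
CXCL11
CXCL13
CXCL9
CXCR3
CXCR4
EOMES
FASLG
FOXP3
GZMA
GZMB
GZMH
GZMK
HAVCR2
HLA-A
HLA-B
HLA-DMA
HLA-DOB
HLA-DRA
HLA-E
ICOS
IDO1
IFNG
IFNGR1
IL10
IL12A
IL12B
IL15
IL18
IL1B
IL2
IL21
IL2RB
IL4
IL6
IL7R
IRF1
ITGAL
KLRD1
LAG3
LCK
NKG7
PDCD1
PDCD1LG2
PRF1
PSMB9
PTPRC
STAT1
STAT4
TAP1
TAP2
TBX21
TGFB1
TIGIT
TNF
VEGFA
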