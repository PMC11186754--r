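TP53
KRAS
EGFR
STK11
KEAP1
IDH1
IDH2
BRAF
MET
ERBB2
PIK3CA
PTEN
RB1
CDKN2A
MYC
NF1
ALK
ROS1
RET
SMARCA4
ARID1A
ATM
BRCA1
BRCA2
SETD2
NOTCH1
FAT1
MGA
RBM10
U2AF1
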