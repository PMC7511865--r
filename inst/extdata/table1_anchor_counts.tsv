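gene	N
SMARCA4	5
ACTG1	4
ARF1	4
GNAS	4
PRDX2	4
SLC25A3	4
SNRPN	4
UBE3A	4
AAK1	3
ARF3	3
ATP5G3	3
ATP5O	3
ATP6V1C1	3
BLVRA	3
CLTA	3
DKK3	3
DSTN	3
EPB41L1	3
GAP43	3
GAPDH	3
IGHG1	3
KLC1	3
LARP1	3
MAP2K4	3
NSFL1C	3
NTRK3	3
OAZ1	3
OBSL1	3
RNF187	3
STMN2	3
TTC3	3
VCP	3
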