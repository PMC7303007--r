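gene	snp_id
NEGR1	rs2422320
MAT2B	rs7714851
ITIH3	rs2535629
CACNA1C	rs4765914
CACNA1C	rs10774037
FHIT	rs1966136
BAG5	rs4906335
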