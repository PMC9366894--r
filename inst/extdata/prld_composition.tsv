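# Amino-acid composition tables for the two-state prion-like-domain HMM.
# prionlike: composition of experimentally characterised yeast prion domains
#   (the Alberti et al. 2009 set underlying PLAAC-style scoring).
# background_human: human reference-proteome amino-acid frequencies (UniProt).
# Columns are normalised to sum to 1 on load.
aa	prionlike	background_human
A	0.0488	0.0702
C	0.0018	0.0230
D	0.0218	0.0474
E	0.0191	0.0710
F	0.0201	0.0365
G	0.0804	0.0658
H	0.0134	0.0263
I	0.0189	0.0433
K	0.0245	0.0573
L	0.0253	0.0996
M	0.0165	0.0213
N	0.1869	0.0359
P	0.0521	0.0631
Q	0.2185	0.0477
R	0.0182	0.0564
S	0.0902	0.0833
T	0.0416	0.0536
V	0.0212	0.0597
W	0.0026	0.0122
Y	0.0618	0.0266
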