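kmer	value
AAA	-36
AAC	-6
AAG	6
AAT	-30
ACA	6
ACC	8
ACG	8
ACT	11
AGA	-9
AGC	25
AGG	8
AGT	11
ATA	-13
ATC	7
ATG	18
ATT	-30
CAA	-9
CAC	17
CAG	-2
CAT	18
CCA	8
CCC	13
CCG	2
CCT	8
CGA	31
CGC	25
CGG	2
CGT	8
CTA	-18
CTC	8
CTG	-2
CTT	6
GAA	-12
GAC	8
GAG	8
GAT	7
GCA	13
GCC	45
GCG	25
GCT	25
GGA	-5
GGC	45
GGG	13
GGT	8
GTA	-6
GTC	8
GTG	17
GTT	-6
TAA	-20
TAC	-6
TAG	-18
TAT	-13
TCA	8
TCC	-5
TCG	31
TCT	-9
TGA	8
TGC	13
TGG	8
TGT	6
TTA	-20
TTC	-12
TTG	-9
TTT	-36
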