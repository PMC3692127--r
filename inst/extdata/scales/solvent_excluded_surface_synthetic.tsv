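kmer	value
AAA	250
AAC	262
AAG	262
AAT	250
ACA	269
ACC	281
ACG	281
ACT	269
AGA	269
AGC	281
AGG	281
AGT	269
ATA	250
ATC	262
ATG	262
ATT	250
CAA	262
CAC	274
CAG	274
CAT	262
CCA	281
CCC	293
CCG	293
CCT	281
CGA	281
CGC	293
CGG	293
CGT	281
CTA	262
CTC	274
CTG	274
CTT	262
GAA	262
GAC	274
GAG	274
GAT	262
GCA	281
GCC	293
GCG	293
GCT	281
GGA	281
GGC	293
GGG	293
GGT	281
GTA	262
GTC	274
GTG	274
GTT	262
TAA	250
TAC	262
TAG	262
TAT	250
TCA	269
TCC	281
TCG	281
TCT	269
TGA	269
TGC	281
TGG	281
TGT	269
TTA	250
TTC	262
TTG	262
TTT	250
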