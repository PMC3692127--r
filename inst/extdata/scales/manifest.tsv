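name	file	order	strand_symmetric	units	citation
bendability	bendability.tsv	3	TRUE	arbitrary bendability units	Brukner I, Sanchez R, Suck D, Pongor S (1995) EMBO J 14:1812-1818
propeller_twist	propeller_twist.tsv	2	TRUE	degrees	el Hassan MA, Calladine CR (1996) J Mol Biol 259:95-103
stacking_energy	stacking_energy.tsv	2	TRUE	kcal/mol	Ornstein RL, Rein R, Breen DL, MacElroy RD (1978) Biopolymers 17:2341-2360
duplex_free_energy	duplex_free_energy.tsv	2	TRUE	kcal/mol	Breslauer KJ, Frank R, Bloecker H, Marky LA (1986) PNAS 83:3746-3750
nucleosome_positioning	nucleosome_positioning.tsv	3	TRUE	percent preference	Satchwell SC, Drew HR, Travers AA (1986) J Mol Biol 191:659-675
solvent_excluded_surface	solvent_excluded_surface_synthetic.tsv	3	TRUE	synthetic area units	synthetic stand-in constructed for this package (not a published scale)
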