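# PI3Kgamma interacting-residue membership (1 = interacting) for XL765, the
# six proposed compounds and the native ligand.
residue	XL765	28	18	38	9	10	19	Native
Lys-802	1	0	0	0	0	0	0	0
Met-804	1	1	1	1	0	1	0	1
Ala-805	0	0	1	0	0	1	1	0
Ser-806	0	1	1	1	1	1	1	0
Lys-807	0	0	0	1	1	0	0	0
Trp-812	1	1	0	1	0	0	0	1
Ile-831	1	1	1	0	1	0	0	1
Lys-833	0	0	1	0	1	1	0	1
Tyr-867	0	0	1	0	0	1	0	1
Ile-879	0	1	1	1	0	1	0	1
Glu-880	0	0	0	0	0	0	0	1
Ile-881	0	0	0	0	0	0	0	1
Val-882	1	0	0	0	0	0	0	1
Ala-885	1	1	0	1	0	0	0	0
Thr-886	1	0	0	0	0	0	0	0
Thr-887	0	1	1	0	0	1	0	1
Lys-890	1	1	1	1	0	1	1	0
Asp-950	0	1	1	1	0	1	1	0
Asn-951	0	1	0	0	0	0	1	0
Met-953	1	1	1	1	0	1	0	1
Ile-963	1	1	1	1	0	1	0	1
Asp-964	0	1	1	1	1	1	1	1
His-967	0	0	0	1	1	0	1	0
His-1089	0	0	0	0	1	0	0	0
Leu-1090	0	0	0	1	1	0	1	0
Val-1091	0	0	0	0	1	0	0	0
Leu-1092	0	0	0	0	1	0	0	0
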