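# mTOR residues interacting with XL765: non-bonded interaction counts,
# hydrogen bonds and buried accessible surface area (A^2) on binding.
residue	n_nonbonded	n_hbonds	delta_asa
Ile-2163	2	0	27.24
Leu-2185	1	0	25.32
Trp-2239	10	0	56.39
Val-2240	1	0	8.9
Asp-2244	3	0	28.52
Thr-2245	1	0	27.82
Ala-2248	1	0	16.09
Arg-2251	6	1	55.76
Asp-2252	3	0	24.43
Met-2345	6	0	30.62
Ile-2356	3	0	31.64
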