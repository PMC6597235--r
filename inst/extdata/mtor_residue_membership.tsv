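# mTOR interacting-residue membership (1 = interacting) for XL765, the six
# proposed compounds and the native ligand.
residue	XL765	28	18	38	9	10	19	Native
Ile-2163	1	0	1	0	0	1	1	1
Thr-2164	0	0	0	0	1	0	0	0
Ser-2165	0	1	0	1	0	0	0	0
Lys-2166	0	0	0	1	0	0	0	0
Gln-2167	0	1	0	1	1	0	0	0
Pro-2169	0	0	0	1	0	1	1	0
Leu-2185	1	1	1	1	1	1	1	1
Lys-2187	0	0	0	1	1	0	1	0
Glu-2190	0	1	0	0	1	0	1	1
Leu-2192	0	0	0	0	0	0	1	0
Asp-2195	0	0	0	0	0	0	1	1
Tyr-2225	0	0	1	0	0	1	1	1
Ile-2237	0	1	1	0	0	1	1	1
Gly-2238	0	1	1	0	1	1	0	1
Trp-2239	1	1	1	1	0	1	1	1
Val-2240	1	1	1	0	1	0	0	1
Cys-2243	0	0	1	0	0	0	0	0
Asp-2244	1	0	1	0	0	0	0	0
Thr-2245	1	0	1	1	0	0	0	0
His-2247	0	0	1	0	0	1	0	0
Ala-2248	1	0	1	0	0	0	0	0
Arg-2251	1	0	1	0	0	0	0	0
Asp-2252	1	0	0	0	0	0	0	0
Ser-2342	0	0	1	0	0	1	0	0
Met-2345	1	1	0	1	1	1	1	0
Ile-2356	1	1	1	1	1	1	1	1
Asp-2357	0	1	0	0	1	0	1	1
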