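# Rule-of-five descriptor values for XL765 and the six proposed dual
# inhibitors (desired values: MW<500, HBD<5, HBA<10, rotatable<10, logP<5).
compound_id	mol_weight	hbd	hba	rotatable_bonds	logp
XL765	599.67	3	9	10	5.76
28	497.53	2	7	6	4.29
18	473.49	4	8	6	3.53
38	690.42	3	8	7	4.73
9	501.55	2	8	8	4.14
10	493.55	4	9	6	3.42
19	491.58	4	9	6	3.18
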