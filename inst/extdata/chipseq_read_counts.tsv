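sample	genotype	fraction	treatment	reads_run1	reads_run2	qc_passed_reads	mapped_reads
wt_input	wt	input	none	6173615	11402103	17521514	16016425
wt_dmso	wt	chip	vehicle	11774655	9298650	20910231	15351905
wt_gw0742	wt	chip	ligand	17489428	10020494	27379614	19552539
null_input	null	input	none	13397018	13963586	27247515	25239456
null_dmso	null	chip	vehicle	9111547	11731976	20625001	14630180
null_gw0742	null	chip	ligand	10955382	11870020	22363483	14770720
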