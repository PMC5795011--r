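# canonical sialylated complex N-glycans, linear encoding
# name<TAB>sequence (rightmost residue attaches to the peptide N-terminus)
mono-sialylated_biantennary	OJUJOJJJOO
di-sialylated_biantennary	OJUUJOJJJOO
mono-sialylated_triantennary	OJUJOJOJJJOO
di-sialylated_triantennary	OJUUJOJOJJJOO
tri-sialylated_triantennary	OJUUJOUJOJJJOO
mono-sialylated_tetraantennary	OJUJOJOJOJJJOO
di-sialylated_tetraantennary	OJUUJOJOJOJJJOO
tri-sialylated_tetraantennary	OJUUJOUJOJOJJJOO
tetra-sialylated_tetraantennary	OJUUJOUJOUJOJJJOO
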