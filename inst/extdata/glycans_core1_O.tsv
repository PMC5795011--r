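# core-1 O-glycans, linear encoding (di-sialylated encoding "UUJO" is one
# of several defensible orderings; only the "UJO" prefix is fixed by the
# b1-b3 oxonium ions)
mono-sialylated_core-1	UJO
di-sialylated_core-1	UUJO
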