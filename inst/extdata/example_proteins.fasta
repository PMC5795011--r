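>SYNGP1 synthetic N-glycoprotein carrying two tryptic sequon peptides
MKQDQCIYNTTYLNVQRENGTISRAAGFLK
>SYNGP2 synthetic O-glycoprotein carrying a Ser/Thr-rich tryptic peptide
MRHTFSGVASVESSSGEAFHVGKLDEK
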