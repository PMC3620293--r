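338F	ACTCCTACGGGAGGCAGC
338F*	ACTYCTACGGRAGGCWGC
341F	CCTACGGGAGGCAGCAG
533R*	TTACCGCGGCKGCTGGCAC
805R	GACTACHVGGGTATCTAATCC
907F	AAACTYAAAKGAATTGACGG
1061R	CRRCACGAGCTGACGAC
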