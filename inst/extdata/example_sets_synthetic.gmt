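DNA_METHYLATION_WRITERS	synthetic example set	DNMT1	DNMT3A	DNMT3B
DNA_METHYLATION_ERASERS	synthetic example set	TET1	TET2	TET3
DNA_METHYLATION_READERS_CORE	synthetic example set	MBD1	MBD2	MBD3	MBD4	MECP2	UHRF1	UHRF2
SYNTHETIC_SIGNAL_BLOCK	synthetic example set	G000025	G000026	G000027	G000028	G000029	G000030
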