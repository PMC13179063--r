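ion_channel_activity	example molecular-function set	Cacna1a	Cacna1b	Cacna1c	Cacna1e	Cacna2d1	Kcnj6	Kcnq2	Kcnma1
ligand_gated_channels	example set	Grin1	Grin2a	Gria1	Gabra1	Gabrb2
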