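class,gene
ca_channel,Cacna1a
ca_channel,Cacna1b
ca_channel,Cacna1c
ca_channel,Cacna1e
ca_channel,Cacna2d1
k_channel,Kcnj6
k_channel,Kcnq2
k_channel,Kcnma1
glutamate_receptor,Grin1
glutamate_receptor,Grin2a
glutamate_receptor,Gria1
gaba_receptor,Gabra1
gaba_receptor,Gabrb2
gaba_receptor,Gabbr1
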