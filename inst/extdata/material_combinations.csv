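liner,socket,combo_tau_min
OttoBock Technogel,thermosetting lay-up,5.4
Iceross Comfort,carbon fibre lay-up,5.5
Iceross Original,carbon fibre lay-up,4.1
Iceross Comfort,thermosetting lay-up,5.8
Alpha Locking,carbon fibre lay-up,6.2
Pe-lite,thermoplastic,6.7
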