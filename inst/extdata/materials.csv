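name,kind,thickness_mm,tau_min
Alpha Locking,liner,6,3.6
Iceross Comfort,liner,6,3.1
Iceross Original,liner,3,2.6
OttoBock Technogel,liner,6,2.8
Pe-lite,liner,5,1.6
stump sock,sock,0.7,0.6
thermoplastic,socket,4.7,4.0
thermosetting lay-up,socket,4,4.1
carbon fibre lay-up,socket,4.8,4.5
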