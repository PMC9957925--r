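# Coin-shaped implant, mode IIa: slide in x under a constant -70 N
# compression, modified Coulomb law, full initial osseointegration.
scenario: csi
test: IIa
law: mc
phi0: 1
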