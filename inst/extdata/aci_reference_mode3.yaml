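# Acetabular cup reference case (E_b = 0.2 GPa, IF = 1 mm, mu_b = 0.3),
# torsional removal under the sustained -2500 N insertion force.
scenario: aci
mode: III
law: mc
E_b: 0.2 GPa
IF: 1 mm
mu_b: 0.3
phi0: 1
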