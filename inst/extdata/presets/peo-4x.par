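# Semidilute-polymer condition: fourfold motility enhancement, small
# concentrated droplet.
DO2 = 2000        # um^2/s
cO2_sat = 250     # uM
K = 1             # uM
K_chi = 7         # uM
kO2_0 = 40000     # molecules s^-1 cell^-1
Dcell_0 = 400     # um^2/s (4x)
chi_0 = 16000    # um^2/s (4x)
c_crit = 0.05     # uM
delta = 0.0166667 # uM
kt = 9.3          # um/s
R = 1400          # um
ccell_0 = 0.04    # cells/um^3 (4e10 cells/mL)
henry_H = 1.5625  # uM/mmHg
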