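# Nutrient-rich (LB) condition: uptake enhanced by active metabolism.
DO2 = 2000        # um^2/s
cO2_sat = 250     # uM
K = 1             # uM
K_chi = 7         # uM
kO2_0 = 300000    # molecules s^-1 cell^-1
Dcell_0 = 100     # um^2/s
chi_0 = 4000    # um^2/s
c_crit = 0.05     # uM
delta = 0.0166667 # uM
kt = 9.3          # um/s
R = 3400          # um
ccell_0 = 0.08    # cells/um^3 (8e10 cells/mL)
henry_H = 1.5625  # uM/mmHg
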