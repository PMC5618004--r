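# Pentagon food-web rate parameters (reference values at 17 degC).
# Y_BC and psi are free parameters of the theory; the values below are the
# package's illustrative configuration, not measured constants:
#   Y_BC = 0.006 nmol-P/nmol-C  (growth efficiency ~0.3 over molar C:P ~50)
#   psi  = 4.63 nmol-C/L/h      (puts the MNL->OCL crossover at
#                                C* = 5 nmol-P/L, ~11.6 ciliates/mL)
alpha_B: 0.08     # L nmol-P^-1 h^-1, prokaryote phosphate affinity
alpha_A: 0.04     # L nmol-P^-1 h^-1, autotroph phosphate affinity
alpha_H: 0.0015   # L nmol-P^-1 h^-1, HNF clearance on prokaryotes
alpha_C: 0.0005   # L nmol-P^-1 h^-1, ciliate clearance on flagellates
Y_H: 0.3          # nmol-P nmol-P^-1, HNF yield on prokaryotes
Y_BC: 0.006       # nmol-P nmol-C^-1, prokaryote yield on DOC (configured)
sigma: 0.00043    # nmol-P cell^-1, P per ciliate (20 um, 0.13 pg-C/um^3, C:P 106)
Q10: 1.3          # temperature sensitivity of the alphas
T_ref: 17         # degC
psi: 4.63         # nmol-C L^-1 h^-1, labile-DOC supply (configured)
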