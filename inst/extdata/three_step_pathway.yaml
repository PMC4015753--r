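# Three-step metabolic pathway: 8 states, 36 parameters, 2 constant controls.
# States x1-x3: mRNA concentrations; x4-x6: enzymes; x7-x8: metabolites.
# Controls: P (pathway product, represses transcription and closes the last
# reaction) and S (substrate, induces transcription and feeds the first
# reaction). Nominal parameters: literature values (0.1 / 1.0 / 2.0 per
# parameter). x0 and default controls are package defaults; the correlation
# structure is independent of the initial state.
name: three_step_pathway
states: [x1, x2, x3, x4, x5, x6, x7, x8]
controls: [P, S]
params: [p1, p2, p3, p4, p5, p6, p7, p8, p9, p10, p11, p12,
         p13, p14, p15, p16, p17, p18, p19, p20, p21, p22, p23, p24,
         p25, p26, p27, p28, p29, p30, p31, p32, p33, p34, p35, p36]
rhs:
  x1: p1/(1 + (P/p2)^p3 + (p4/S)^p5) - p6*x1
  x2: p7/(1 + (P/p8)^p9 + (p10/x7)^p11) - p12*x2
  x3: p13/(1 + (P/p14)^p15 + (p16/x8)^p17) - p18*x3
  x4: p19*x1/(p20 + x1) - p21*x4
  x5: p22*x2/(p23 + x2) - p24*x5
  x6: p25*x3/(p26 + x3) - p27*x6
  x7: p28*x4*(S - x7)/(p29*(1 + S/p29 + x7/p30)) - p31*x5*(x7 - x8)/(p32*(1 + x7/p32 + x8/p33))
  x8: p31*x5*(x7 - x8)/(p32*(1 + x7/p32 + x8/p33)) - p34*x6*(x8 - P)/(p35*(1 + x8/p35 + P/p36))
nominal:
  p: [1.0, 1.0, 2.0, 1.0, 2.0, 1.0,
      1.0, 1.0, 2.0, 1.0, 2.0, 1.0,
      1.0, 1.0, 2.0, 1.0, 2.0, 1.0,
      0.1, 1.0, 0.1,
      0.1, 1.0, 0.1,
      0.1, 1.0, 0.1,
      1.0, 1.0, 1.0,
      1.0, 1.0, 1.0,
      1.0, 1.0, 1.0]
  x0: [0.667, 0.667, 0.667, 0.667, 0.667, 0.667, 0.667, 0.667]
  u: [0.7, 1.4]
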