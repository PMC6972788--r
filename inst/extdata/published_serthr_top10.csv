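# Top-10 ranked serine/threonine kinases of a published endurance-training
# lymphocyte kinome profiling study (transcribed printed summary table;
# decimal-comma dialect as printed). Columns: median final score Q,
# specificity score Qsp, normalized median kinase statistic s.
kinase;Q;Qsp;s
PKG2;4,08;2,61;-0,42
IKKa;4,00;2,06;-0,72
PKG1;3,92;2,65;-0,39
CaMK4;3,92;2,43;-0,52
PKAa;3,88;2,67;-0,37
p70S6Kb;3,67;2,27;-0,43
PRKX;3,40;1,99;-0,34
PKCa;2,92;1,73;-0,37
CK2a1;2,51;0,92;-0,51
PKCd;2,38;1,33;-0,34
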