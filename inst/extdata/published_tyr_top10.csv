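# Top-10 ranked tyrosine kinases of a published endurance-training lymphocyte
# kinome profiling study (transcribed printed summary table; decimal-comma
# dialect as printed). Columns: median final score Q, specificity score Qsp,
# normalized median kinase statistic s.
kinase;Q;Qsp;s
FGFR3;3,80;2,40;0,58
FGFR2;3,62;2,42;0,57
FGFR4;3,34;2,00;0,49
FGFR1;2,63;1,41;0,47
ZAP70;2,50;1,61;0,43
FLT3;1,98;0,93;0,46
Met;1,90;0,98;0,44
CSK;1,79;0,92;0,42
FAK1;1,65;0,58;0,42
Syk;1,61;0,71;0,41
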