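# Phosphatidylethanolamine (PE), positive mode, neutral-loss scanning.
# Precursor = [M+H]+ molecular cation; the fragment is the precursor after
# the facile loss of the phosphoethanolamine head group (delta m/z 141.02).
QUERYNAME = PE;
DEFINE prPE = 'C[28..50] H[30..105] N[1..1] O[8..8] P[1..1]' WITH DBR = (1.5, 13.5), CHG = +1;
DEFINE NL1 = 'C[26..48] H[25..95] O[4..4]' WITH DBR = (2.5, 14.5), CHG = +1;
IDENTIFY prPE IN MS1+, NL1 IN MS2+;
SUCHTHAT NL1.chemsc + C2H8N1O4P1 == PR.chemsc;
REPORT MASS = PR.mass;
REPORT CHEMSC = PR.chemsc;
REPORT INTENS = PR.intensity;
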