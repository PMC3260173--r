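# Phosphatidylethanolamine (PE), negative mode.
# Precursor = [M-H]- molecular anion; fragments = the two acyl anions.
# Works unchanged on DDA MasterScans and on MasterScans built from
# transposed precursor-ion scans.
QUERYNAME = PE;
DEFINE prPE = 'C[28..50] H[30..100] N[1..1] O[8..8] P[1..1]' WITH DBR = (2.5, 14.5), CHG = -1;
DEFINE FA1 = 'C[12..22] H[11..43] O[2..2]' WITH DBR = (1.5, 7.5), CHG = -1;
DEFINE FA2 = 'C[12..22] H[11..43] O[2..2]' WITH DBR = (1.5, 7.5), CHG = -1;
IDENTIFY prPE IN MS1-, FA1 IN MS2-, FA2 IN MS2-;
# both acyl moieties plus the phosphoethanolamine head group and glycerol
# backbone must add up to the sum composition of the intact precursor
SUCHTHAT FA1.chemsc + FA2.chemsc + C5H11O4N1P1 == PR.chemsc;
REPORT MASS = PR.mass;
REPORT CHEMSC = PR.chemsc;
REPORT INTENS = PR.intensity;
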