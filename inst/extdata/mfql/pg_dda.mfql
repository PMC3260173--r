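# Phosphatidylglycerol (PG), negative mode.
# Precursor = [M-H]- molecular anion; fragments = the two acyl anions.
QUERYNAME = PG;
DEFINE prPG = 'C[29..51] H[30..100] N[0..0] O[10..10] P[1..1]' WITH DBR = (2.5, 14.5), CHG = -1;
DEFINE FA1 = 'C[12..22] H[11..43] O[2..2]' WITH DBR = (1.5, 7.5), CHG = -1;
DEFINE FA2 = 'C[12..22] H[11..43] O[2..2]' WITH DBR = (1.5, 7.5), CHG = -1;
IDENTIFY prPG IN MS1-, FA1 IN MS2-, FA2 IN MS2-;
SUCHTHAT FA1.chemsc + FA2.chemsc + C6H12O6P1 == PR.chemsc;
REPORT MASS = PR.mass;
REPORT CHEMSC = PR.chemsc;
REPORT INTENS = PR.intensity;
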