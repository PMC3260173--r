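# Phosphatidylglycerol (PG), positive mode, neutral-loss scanning.
# Precursor = [M+NH4]+ ammonium adduct; the fragment is the precursor after
# the loss of the head group plus ammonia (delta m/z 189.04).
QUERYNAME = PG;
DEFINE prPG = 'C[29..51] H[35..105] N[1..1] O[10..10] P[1..1]' WITH DBR = (0.5, 12.5), CHG = +1;
DEFINE NL1 = 'C[26..48] H[25..95] O[4..4]' WITH DBR = (2.5, 14.5), CHG = +1;
IDENTIFY prPG IN MS1+, NL1 IN MS2+;
SUCHTHAT NL1.chemsc + C3H12N1O6P1 == PR.chemsc;
REPORT MASS = PR.mass;
REPORT CHEMSC = PR.chemsc;
REPORT INTENS = PR.intensity;
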