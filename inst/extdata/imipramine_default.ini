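# phsolv model configuration

[constants]
pKa = 9.52
pKw = 13.764
pKa1 = 1.95
pKa2 = 6.74
pKa3 = 11.6
pS0 = 4.602
pKsp_BHCl = 2.338
pKsp_BHH2PO4 = 2.823
pKsp_BH2HPO4 = 6.812
logK310 = 8.728
logK750 = 9.97
logK141 = 0.374

[fixed]
pKa = true
pKw = true
pKa1 = true
pKa2 = true
pKa3 = true
pS0 = true
pKsp_BHCl = true
pKsp_BHH2PO4 = true
pKsp_BH2HPO4 = true
logK310 = true
logK750 = true
logK141 = true

[activity]
form = davies
A_DH = 0.509
Ks_neutral = 0.42
I_ref = 0.15

[electrode]
alpha = 0
ks = 1
jH = 0
jOH = 0
pKw = 13.764
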