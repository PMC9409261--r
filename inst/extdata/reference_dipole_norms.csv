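table,quantity,model,pair,norm_debye
A,muCO,WH,4-1,1.3523
A,muCO,WH,4-2,1.3268
A,muCO,WH,4-3,1.3509
A,muCO,ST,4-1,1.3641
A,muCO,ST,4-2,1.3877
A,muCO,ST,4-3,1.3805
A,muCO,MH,4-1,1.3938
A,muCO,MH,4-2,1.4236
A,muCO,MH,4-3,1.4139
A,muHN,WH,4-1,0.5232
A,muHN,WH,4-2,0.5386
A,muHN,WH,4-3,0.5328
A,muHN,ST,4-1,0.5211
A,muHN,ST,4-2,0.5283
A,muHN,ST,4-3,0.5293
A,muHN,MH,4-1,0.5371
A,muHN,MH,4-2,0.5459
A,muHN,MH,4-3,0.5476
B,muCO,WH,4-1,1.3847
B,muCO,WH,4-2,1.3471
B,muCO,WH,4-3,1.3883
B,muCO,ST,4-1,1.4026
B,muCO,ST,4-2,1.4150
B,muCO,ST,4-3,1.4202
B,muCO,MH,4-1,1.4411
B,muCO,MH,4-2,1.4594
B,muCO,MH,4-3,1.4625
B,muHN,WH,4-1,0.5825
B,muHN,WH,4-2,0.5873
B,muHN,WH,4-3,0.6011
B,muHN,ST,4-1,0.5865
B,muHN,ST,4-2,0.5890
B,muHN,ST,4-3,0.6003
B,muHN,MH,4-1,0.6194
B,muHN,MH,4-2,0.6205
B,muHN,MH,4-3,0.6328
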