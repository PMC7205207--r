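name,fv_charge,cdr_charge,dna_score,insulin_score,acsins_score
AB-001,-2.01,-3.7,2,2,22
R1-016,0.93,-2.7,2,4,24
R2-001,3.87,-2.7,2,6,24
R2-006,4.87,-1.7,2,6,25
R2-020,4.85,-1.7,3,5,4
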