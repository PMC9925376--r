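rank,hap1,hap2,collapse3
1,CYP2C:TG,CYP2C19*17,lower-exposure
2,CYP2C19*17,CYP2C19*17,lower-exposure
3,CYP2C:TG,CYP2C:TG,lower-exposure
4,CYP2C:TG,CYP2C:CG-or-TA,lower-exposure
5,CYP2C19*17,CYP2C:CG-or-TA,lower-exposure
6,CYP2C:CG-or-TA,CYP2C:CG-or-TA,reference
7,CYP2C:TG,CYP2C19null,higher-exposure
8,CYP2C19*17,CYP2C19null,higher-exposure
9,CYP2C:CG-or-TA,CYP2C19null,higher-exposure
10,CYP2C19null,CYP2C19null,higher-exposure
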