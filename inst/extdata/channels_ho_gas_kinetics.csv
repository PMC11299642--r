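site,mechanism,radical,dG_rxn,dG_act,kappa,sigma,nu_imag,v_forward,v_reverse,k_ref
C23-H,FHT,HO,-21.7,4.1,2.5,3,,,,4.94e10
C24-H,FHT,HO,-16.4,11.0,5.2,3,,,,7.83e5
C2,RAF,HO,-5.0,10.1,1.5,1,,,,3.67e5
C4,RAF,HO,4.2,13.4,1.4,1,,,,1.26e3
C5,RAF,HO,-19,7.2,1.2,1,,,,3.98e7
C6,RAF,HO,-9.3,7.6,1.2,1,,,,1.87e7
C7,RAF,HO,-10.9,7.3,1.2,1,,,,3.31e7
C8,RAF,HO,-15.5,6.5,1.2,1,,,,1.23e8
C9,RAF,HO,1.5,13.1,1.4,1,,,,2.35e3
C11,RAF,HO,-6.9,10.0,1.4,1,,,,4.04e5
C12,RAF,HO,-20.7,2.3,1.2,1,,,,1.45e11
C13,RAF,HO,-24.5,2.8,1.3,1,,,,7.60e10
C14,RAF,HO,-9.5,12.7,1.5,1,,,,4.52e3
C15,RAF,HO,-10.2,6.8,1.0,1,,,,6.63e7
C16,RAF,HO,-6.1,8.8,1.3,1,,,,3.13e6
C18,RAF,HO,-5.2,8.4,1.4,1,,,,6.63e6
C19,RAF,HO,-9.8,13.4,1.4,1,,,,1.14e3
C25,RAF,HO,-2.7,12.7,1.3,1,,,,3.85e3
C26,RAF,HO,-8.3,6.8,1.2,1,,,,7.95e7
C27,RAF,HO,-5.8,9.0,1.3,1,,,,2.05e6
C28,RAF,HO,-8.2,7.4,1.3,1,,,,3.01e7
C29,RAF,HO,-5.5,8.0,1.3,1,,,,1.02e7
C30,RAF,HO,-9.4,6.8,1.2,1,,,,7.95e7
N10,RAF,HO,-2.5,10.3,1.7,1,,,,2.95e5
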