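site,mechanism,radical,dG_rxn,dG_act,kappa,sigma,nu_imag,v_forward,v_reverse
C23-H,FHT,HO,-21.7,,,1,,,
C24-H,FHT,HO,-16.4,,,1,,,
C2,RAF,HO,-5.0,,,1,,,
C4,RAF,HO,4.2,,,1,,,
C5,RAF,HO,-19,,,1,,,
C6,RAF,HO,-9.3,,,1,,,
C7,RAF,HO,-10.9,,,1,,,
C8,RAF,HO,-15.5,,,1,,,
C9,RAF,HO,1.5,,,1,,,
C11,RAF,HO,-6.9,,,1,,,
C12,RAF,HO,-20.7,,,1,,,
C13,RAF,HO,-24.5,,,1,,,
C14,RAF,HO,-9.5,,,1,,,
C15,RAF,HO,-10.2,,,1,,,
C16,RAF,HO,-6.1,,,1,,,
C17,RAF,HO,-7.2,,,1,,,
C18,RAF,HO,-5.2,,,1,,,
C19,RAF,HO,-9.8,,,1,,,
C25,RAF,HO,-2.7,,,1,,,
C26,RAF,HO,-8.3,,,1,,,
C27,RAF,HO,-5.8,,,1,,,
C28,RAF,HO,-8.2,,,1,,,
C29,RAF,HO,-5.5,,,1,,,
C30,RAF,HO,-9.4,,,1,,,
N3,RAF,HO,13.8,,,1,,,
N10,RAF,HO,-2.5,,,1,,,
SET,SET,HO,155.6,,,1,,,
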