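site,mechanism,radical,dG_rxn,dG_act,kappa,sigma,nu_imag,v_forward,v_reverse,k_ref
C23-H,FHT,HO,-21.7,6.0,2.1,1,,,,4.10e8
C12,RAF,HO,-20.7,5.6,1.1,1,,,,4.40e8
C13,RAF,HO,-24.5,8.3,1.1,1,,,,5.60e6
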