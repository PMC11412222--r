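((Outgroupus_primus,Zeta_commentica),((Alpha_exempli,Beta_exempli),(Gamma_ficta,(Delta_ficta,Epsilon_ficta))));
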