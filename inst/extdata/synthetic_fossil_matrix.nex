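#NEXUS
[ Synthetic example matrix: 8 taxa x 12 discrete characters, written by hand
  for documentation and tests. Fossilis_synthetica is a made-up fossil with
  heavy missingness; it is NOT data from any real study. ]
BEGIN DATA;
  DIMENSIONS NTAX=8 NCHAR=12;
  FORMAT SYMBOLS="0 1 2" MISSING=? GAP=-;
  MATRIX
    Outgroupus_primus     000000 000000
    Alpha_exempli         100100 010000
    Beta_exempli          100100 010010
    Gamma_ficta           101100 110010
    Delta_ficta           1011{01}0 110011
    Epsilon_ficta         101110 1-0011
    Zeta_commentica       001110 200011
    Fossilis_synthetica   10111? ??0-11
  ;
END;
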