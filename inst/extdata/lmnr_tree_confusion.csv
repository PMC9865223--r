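classified,crops,scrub_grass,pinus_tabuliformis,quercus_wutaishanica,pine_oak_mixed,larix_principis,shaw
crops,62,0,0,0,0,0,0
scrub_grass,0,72,0,0,0,0,0
pinus_tabuliformis,0,0,117,0,0,0,0
quercus_wutaishanica,1,0,0,125,9,0,0
pine_oak_mixed,0,0,0,0,108,14,3
larix_principis,0,0,0,1,0,58,0
shaw,0,0,0,0,0,0,60
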