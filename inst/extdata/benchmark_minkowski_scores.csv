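dataset,semi_ps,semi_euc,feaclus,vamosa,vgaps,kmeans
iris,0.39,0.39,0.44,0.80,0.62,0.68
cancer,0.31,0.37,0.31,0.32,0.37,0.37
newthyroid,0.46,0.47,0.54,0.57,0.58,0.94
wine,0.62,0.64,0.67,0.97,1.12,1.40
liverdisorder,0.64,0.98,0.98,0.98,0.98,0.98
lungcancer,0.70,0.71,0.70,0.85,1.24,1.45
glass,1.03,1.05,1.05,1.08,1.10,1.69
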