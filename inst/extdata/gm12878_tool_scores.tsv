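tool	consistency_pct	biological_pct
LASCA	0.2714	0.3176
cLoops	1.2360	21.8354
cLoops2	1.9832	3.2262
HiCCUPS	6.0684	6.7759
HiCExplorer	4.0634	3.8357
FitHiC2	0.1634	0.4064
FitHiChIP	2.8674	5.6856
Peakachu	3.9576	4.1083
Mustache	2.8582	1.5807
Chromosight	1.6618	6.3758
SIP	3.0936	7.7147
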