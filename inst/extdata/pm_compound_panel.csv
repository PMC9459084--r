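compound,name,class
X1,Catechin,flavanol
X2,Epicatechin,flavanol
X3,Torachrysone-8-O-beta-D-glucopyranoside,anthraquinone glycoside
X4,7-acetyl-3-8-dihydroxy-6-methyl-1-naphthyl-beta-D-glucopyranoside,anthraquinone glycoside
X5,Epicatechin-3-O-gallate,flavanol
X6,Emodin-8-O-beta-D-glucopyranoside,anthraquinone glycoside
X7,Emodin bianthrones,dianthrone
X8,Emodin-physcion bianthrones,dianthrone
X9,Physcion bianthrones,dianthrone
X10,2-3-5-4'-tetrahydroxystilbene-2-O-beta-D-(2-O-monogalloylesters)-glucopyranoside,stilbene glycoside
X11,Polygonibene E,stilbene glycoside
X12,Polygonumnolides C1-C4,dianthrone
X13,Polygonumnolides A1-A4,dianthrone
X14,PM 14-17,dianthrone
X15,PM 22-25,dianthrone
X16,PM 5,dianthrone
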