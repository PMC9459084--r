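compound,rt_mz,vip,p_value,fc
Catechin,4.88_289.0716,11.03,1.50e-6,0.286
Epicatechin,7.89_290.0786n,4.08,4.60e-4,0.397
Torachrysone-8-O-beta-D-glucopyranoside,23.71_408.1413n,9.99,1.00e-9,0.225
7-acetyl-3-8-dihydroxy-6-methyl-1-naphthyl-beta-D-glucopyranoside,17.97_393.1173,3.48,2.42e-10,0.137
Epicatechin-3-O-gallate,11.59_442.0917n,7.44,9.32e-5,0.328
Emodin-8-O-beta-D-glucopyranoside,25.61_431.2031,2.47,1.75e-8,0.441
2-3-5-4'-tetrahydroxystilbene-2-O-beta-D-(2-O-monogalloylesters)-glucopyranoside,14.58_558.1371n,13.36,5.97e-5,0.359
Polygonibene E,22.91_582.1726n,5.56,2.50e-7,0.366
Polygonumnolides C1-C4,32.40_671.1733,1.83,5.55e-3,0.380
Polygonumnolides A1-A4,34.95_685.1887,2.06,3.15e-3,0.366
PM 14-17,30.37_758.1799n,1.59,2.04e-3,0.157
PM 22-25,27.64_933.2410,1.86,7.60e-5,0.186
PM 5,27.10_920.2342n,1.77,1.23e-4,0.180
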