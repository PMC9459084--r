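compound,gra_L02,gra_HepG2,opls_r_L02,opls_r_HepG2,garson_L02,garson_HepG2,miv_L02,miv_HepG2
X1,0.763,0.754,0.873,0.478,4.07,7.57,0.009,0.015
X2,0.818,0.778,-0.285,0.061,5.01,9.43,-0.029,0.004
X3,0.806,0.813,0.193,-0.055,7.29,5.69,0.105,0.029
X4,0.804,0.816,-0.062,-0.150,7.03,6.51,-0.046,-0.131
X5,0.825,0.814,-0.515,-0.510,6.60,4.08,0.002,0.062
X6,0.826,0.776,-0.387,-0.210,7.35,6.05,-0.089,-0.023
X7,0.755,0.718,-0.443,-0.222,6.40,7.40,-0.161,-0.247
X8,0.750,0.707,0.160,0.070,8.50,6.19,0.086,0.145
X9,0.718,0.681,-0.101,-0.190,4.99,6.21,-0.038,0.020
X10,0.800,0.776,-0.266,-0.318,7.61,6.63,-0.055,0.033
X11,0.786,0.769,-0.191,-0.062,5.77,6.19,0.022,-0.103
X12,0.733,0.715,0.504,0.506,8.12,5.91,0.072,0.178
X13,0.744,0.755,0.239,0.198,5.47,6.07,0.002,-0.102
X14,0.772,0.779,-0.597,-0.440,4.88,5.32,-0.015,-0.006
X15,0.750,0.774,0.048,-0.121,5.70,4.95,-0.040,0.004
X16,0.755,0.775,-0.272,-0.252,5.22,5.79,-0.013,0.032
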