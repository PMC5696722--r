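# element: Ar  Z: 18  A: 39.9480
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 6.073971e+01 5.971741e+01 5.971414e+01 1.737923e-01 8.517761e-01
10.5607 5.150809e+01 5.056387e+01 5.056044e+01 1.734346e-01 7.742142e-01
11.1529 4.368670e+01 4.281353e+01 4.280992e+01 1.730589e-01 7.037150e-01
11.7783 3.705980e+01 3.625129e+01 3.624750e+01 1.726645e-01 6.396354e-01
12.4387 3.144468e+01 3.069502e+01 3.069104e+01 1.722505e-01 5.813908e-01
13.1362 2.668661e+01 2.599053e+01 2.598635e+01 1.718162e-01 5.284499e-01
13.8728 2.265454e+01 2.200724e+01 2.200285e+01 1.713606e-01 4.803298e-01
14.6507 1.923746e+01 1.863459e+01 1.862998e+01 1.708829e-01 4.365914e-01
15.4722 1.634137e+01 1.577899e+01 1.577415e+01 1.703823e-01 3.968358e-01
16.3397 1.388666e+01 1.336118e+01 1.335610e+01 1.698578e-01 3.607003e-01
17.2560 1.180588e+01 1.131404e+01 1.130872e+01 1.693086e-01 3.278553e-01
18.2235 1.004191e+01 9.580761e+00 9.575179e+00 1.687336e-01 2.980011e-01
19.2454 8.546377e+00 8.113230e+00 8.107380e+00 1.681320e-01 2.708654e-01
20.3245 7.278286e+00 6.870711e+00 6.864583e+00 1.675029e-01 2.462007e-01
21.4642 6.202923e+00 5.818714e+00 5.812296e+00 1.668452e-01 2.237819e-01
22.6678 5.290880e+00 4.928036e+00 4.921317e+00 1.661582e-01 2.034045e-01
23.9388 4.517242e+00 4.173948e+00 4.166918e+00 1.654407e-01 1.848827e-01
25.2811 3.860902e+00 3.535515e+00 3.528162e+00 1.646920e-01 1.680475e-01
26.6987 3.303979e+00 2.995009e+00 2.987323e+00 1.639112e-01 1.527452e-01
28.1958 2.831324e+00 2.537421e+00 2.529390e+00 1.630972e-01 1.388364e-01
29.7768 2.430098e+00 2.150042e+00 2.141654e+00 1.622494e-01 1.261941e-01
31.4465 2.089425e+00 1.822110e+00 1.813356e+00 1.613668e-01 1.147030e-01
33.2098 1.800090e+00 1.544515e+00 1.535383e+00 1.604486e-01 1.042582e-01
35.0719 1.554279e+00 1.309542e+00 1.300021e+00 1.594942e-01 9.476458e-02
37.0385 1.345376e+00 1.110659e+00 1.100738e+00 1.585029e-01 8.613541e-02
39.1154 1.167769e+00 9.423349e-01 9.320033e-01 1.574740e-01 7.829200e-02
41.3087 1.016704e+00 7.998864e-01 7.891346e-01 1.564069e-01 7.116281e-02
43.6250 8.881505e-01 6.793483e-01 6.681665e-01 1.553012e-01 6.468279e-02
46.0712 7.786911e-01 5.773629e-01 5.657418e-01 1.541565e-01 5.879284e-02
48.6545 6.854297e-01 4.910873e-01 4.790181e-01 1.529724e-01 5.343922e-02
51.3827 6.059102e-01 4.181139e-01 4.055884e-01 1.517487e-01 4.857310e-02
54.2639 5.380503e-01 3.564043e-01 3.434149e-01 1.504853e-01 4.415008e-02
57.3066 4.800841e-01 3.042322e-01 2.907721e-01 1.491822e-01 4.012981e-02
60.5200 4.305142e-01 2.601361e-01 2.461990e-01 1.478395e-01 3.647563e-02
63.9135 3.880703e-01 2.228779e-01 2.084587e-01 1.464575e-01 3.315420e-02
67.4973 3.516752e-01 1.914095e-01 1.765036e-01 1.450364e-01 3.013521e-02
71.2821 3.204149e-01 1.648430e-01 1.494470e-01 1.435767e-01 2.739112e-02
75.2791 2.935141e-01 1.424265e-01 1.265379e-01 1.420792e-01 2.489691e-02
79.5002 2.703151e-01 1.235232e-01 1.071407e-01 1.405446e-01 2.262983e-02
83.9580 2.502597e-01 1.075937e-01 9.071686e-02 1.389737e-01 2.056918e-02
88.6658 2.328744e-01 9.418111e-02 7.681068e-02 1.373676e-01 1.869617e-02
93.6375 2.177574e-01 8.289823e-02 6.503621e-02 1.357274e-01 1.699371e-02
98.8880 2.045675e-01 7.341715e-02 5.506667e-02 1.340546e-01 1.544628e-02
104.4330 1.930156e-01 6.546000e-02 4.662539e-02 1.323505e-01 1.403976e-02
110.2888 1.828560e-01 5.879130e-02 3.947808e-02 1.306166e-01 1.276131e-02
116.4730 1.738804e-01 5.321150e-02 3.342640e-02 1.288548e-01 1.159928e-02
123.0040 1.659121e-01 4.855147e-02 2.830240e-02 1.270666e-01 1.054306e-02
129.9012 1.588010e-01 4.466783e-02 2.396387e-02 1.252541e-01 9.583018e-03
137.1852 1.524201e-01 4.143904e-02 2.029039e-02 1.234193e-01 8.710398e-03
144.8775 1.466613e-01 3.876205e-02 1.718004e-02 1.215640e-01 7.917237e-03
153.0012 1.414333e-01 3.654949e-02 1.454647e-02 1.196905e-01 7.196301e-03
161.5805 1.366586e-01 3.472725e-02 1.231661e-02 1.178009e-01 6.541013e-03
170.6407 1.322714e-01 3.323252e-02 1.042857e-02 1.158974e-01 5.945395e-03
180.2091 1.282161e-01 3.201199e-02 8.829956e-03 1.139821e-01 5.404013e-03
190.3139 1.244457e-01 3.102049e-02 7.476393e-03 1.120573e-01 4.911929e-03
200.9854 1.209201e-01 3.021971e-02 6.330321e-03 1.101251e-01 4.464653e-03
212.2552 1.176058e-01 2.957713e-02 5.359933e-03 1.081877e-01 4.058106e-03
224.1570 1.144740e-01 2.906524e-02 4.538298e-03 1.062472e-01 3.688579e-03
236.7261 1.115008e-01 2.866067e-02 3.842612e-03 1.043055e-01 3.352701e-03
250.0000 1.086657e-01 2.834364e-02 3.253570e-03 1.023647e-01 3.047407e-03
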