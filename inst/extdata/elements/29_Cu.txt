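# element: Cu  Z: 29  A: 63.5460
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 2.756995e+02 2.737626e+02 2.737593e+02 1.760203e-01 1.764193e+00
10.5607 2.335733e+02 2.317976e+02 2.317941e+02 1.756580e-01 1.603547e+00
11.1529 1.978947e+02 1.962656e+02 1.962619e+02 1.752775e-01 1.457530e+00
11.7783 1.676762e+02 1.661804e+02 1.661765e+02 1.748780e-01 1.324808e+00
12.4387 1.420816e+02 1.407070e+02 1.407030e+02 1.744588e-01 1.204173e+00
13.1362 1.204029e+02 1.191386e+02 1.191343e+02 1.740189e-01 1.094522e+00
13.8728 1.020404e+02 1.008764e+02 1.008720e+02 1.735575e-01 9.948557e-01
14.6507 8.648643e+01 8.541376e+01 8.540909e+01 1.730737e-01 9.042651e-01
15.4722 7.331104e+01 7.232145e+01 7.231655e+01 1.725666e-01 8.219236e-01
16.3397 6.215011e+01 6.123614e+01 6.123100e+01 1.720354e-01 7.470800e-01
17.2560 5.269530e+01 5.185016e+01 5.184477e+01 1.714791e-01 6.790516e-01
18.2235 4.468549e+01 4.390303e+01 4.389737e+01 1.708968e-01 6.172178e-01
19.2454 3.789956e+01 3.717418e+01 3.716825e+01 1.702875e-01 5.610146e-01
20.3245 3.215023e+01 3.147686e+01 3.147065e+01 1.696503e-01 5.099291e-01
21.4642 2.727893e+01 2.665295e+01 2.664645e+01 1.689842e-01 4.634955e-01
22.6678 2.315134e+01 2.256857e+01 2.256176e+01 1.682883e-01 4.212900e-01
23.9388 1.965371e+01 1.911034e+01 1.910322e+01 1.675617e-01 3.829278e-01
25.2811 1.668971e+01 1.618229e+01 1.617485e+01 1.668034e-01 3.480587e-01
26.6987 1.417775e+01 1.370316e+01 1.369537e+01 1.660125e-01 3.163648e-01
28.1958 1.204872e+01 1.160411e+01 1.159598e+01 1.651881e-01 2.875570e-01
29.7768 1.024411e+01 9.826902e+00 9.818407e+00 1.643294e-01 2.613723e-01
31.4465 8.714330e+00 8.322189e+00 8.313323e+00 1.634355e-01 2.375720e-01
33.2098 7.417401e+00 7.048206e+00 7.038956e+00 1.625056e-01 2.159389e-01
35.0719 6.317754e+00 5.969583e+00 5.959940e+00 1.615390e-01 1.962757e-01
37.0385 5.385266e+00 5.056377e+00 5.046328e+00 1.605349e-01 1.784031e-01
39.1154 4.594416e+00 4.283230e+00 4.272766e+00 1.594928e-01 1.621578e-01
41.3087 3.923588e+00 3.628674e+00 3.617784e+00 1.584121e-01 1.473919e-01
43.6250 3.354469e+00 3.074532e+00 3.063207e+00 1.572922e-01 1.339705e-01
46.0712 2.871545e+00 2.605411e+00 2.593641e+00 1.561328e-01 1.217713e-01
48.6545 2.461673e+00 2.208280e+00 2.196057e+00 1.549335e-01 1.106829e-01
51.3827 2.113717e+00 1.872104e+00 1.859418e+00 1.536941e-01 1.006043e-01
54.2639 1.818242e+00 1.587540e+00 1.574384e+00 1.524146e-01 9.144333e-02
57.3066 1.567255e+00 1.346676e+00 1.333044e+00 1.510948e-01 8.311659e-02
60.5200 1.353981e+00 1.142814e+00 1.128699e+00 1.497348e-01 7.554807e-02
63.9135 1.172682e+00 9.702821e-01 9.556780e-01 1.483351e-01 6.866874e-02
67.4973 1.018492e+00 8.242771e-01 8.091801e-01 1.468957e-01 6.241583e-02
71.2821 8.872889e-01 7.007325e-01 6.851392e-01 1.454174e-01 5.673230e-02
75.2791 7.755797e-01 5.962050e-01 5.801127e-01 1.439007e-01 5.156631e-02
79.5002 6.804031e-01 5.077786e-01 4.911860e-01 1.423464e-01 4.687074e-02
83.9580 5.992492e-01 4.329843e-01 4.158911e-01 1.407553e-01 4.260273e-02
88.6658 5.299903e-01 3.697314e-01 3.521383e-01 1.391286e-01 3.872337e-02
93.6375 4.708230e-01 3.162493e-01 2.981583e-01 1.374675e-01 3.519726e-02
98.8880 4.202184e-01 2.710387e-01 2.524529e-01 1.357732e-01 3.199223e-02
104.4330 3.768802e-01 2.328300e-01 2.137539e-01 1.340472e-01 2.907905e-02
110.2888 3.397094e-01 2.005479e-01 1.809871e-01 1.322911e-01 2.643114e-02
116.4730 3.077743e-01 1.732820e-01 1.532432e-01 1.305067e-01 2.402434e-02
123.0040 2.802846e-01 1.502609e-01 1.297522e-01 1.286956e-01 2.183671e-02
129.9012 2.565704e-01 1.308316e-01 1.098623e-01 1.268599e-01 1.984828e-02
137.1852 2.360637e-01 1.144410e-01 9.302124e-02 1.250015e-01 1.804091e-02
144.8775 2.182824e-01 1.006205e-01 7.876182e-02 1.231225e-01 1.639813e-02
153.0012 2.028182e-01 8.897335e-02 6.668825e-02 1.212250e-01 1.490493e-02
161.5805 1.893243e-01 7.916341e-02 5.646547e-02 1.193112e-01 1.354770e-02
170.6407 1.775070e-01 7.090605e-02 4.780976e-02 1.173832e-01 1.231406e-02
180.2091 1.671171e-01 6.396013e-02 4.048090e-02 1.154434e-01 1.119275e-02
190.3139 1.579430e-01 5.812144e-02 3.427550e-02 1.134939e-01 1.017355e-02
200.9854 1.498054e-01 5.321698e-02 2.902133e-02 1.115370e-01 9.247158e-03
212.2552 1.425524e-01 4.910026e-02 2.457259e-02 1.095747e-01 8.405121e-03
224.1570 1.360548e-01 4.564719e-02 2.080581e-02 1.076093e-01 7.639759e-03
236.7261 1.302033e-01 4.275267e-02 1.761644e-02 1.056427e-01 6.944090e-03
250.0000 1.249048e-01 4.032771e-02 1.491598e-02 1.036771e-01 6.311768e-03
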