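# element: B  Z: 5  A: 10.8110
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 1.368444e+00 1.065410e+00 1.062063e+00 1.783845e-01 1.279966e-01
10.5607 1.193616e+00 9.027763e-01 8.992569e-01 1.780174e-01 1.163413e-01
11.1529 1.044787e+00 7.651076e-01 7.614079e-01 1.776317e-01 1.057474e-01
11.7783 9.180352e-01 6.485784e-01 6.446901e-01 1.772269e-01 9.611815e-02
12.4387 8.100319e-01 5.499497e-01 5.458642e-01 1.768020e-01 8.736573e-02
13.1362 7.179540e-01 4.664791e-01 4.621875e-01 1.763562e-01 7.941029e-02
13.8728 6.394057e-01 3.958446e-01 3.913378e-01 1.758886e-01 7.217926e-02
14.6507 5.723538e-01 3.360802e-01 3.313488e-01 1.753983e-01 6.560669e-02
15.4722 5.150727e-01 2.855213e-01 2.805557e-01 1.748845e-01 5.963261e-02
16.3397 4.660973e-01 2.427585e-01 2.375487e-01 1.743461e-01 5.420252e-02
17.2560 4.241836e-01 2.065985e-01 2.011344e-01 1.737823e-01 4.926689e-02
18.2235 3.882749e-01 1.760309e-01 1.703021e-01 1.731922e-01 4.478070e-02
19.2454 3.574738e-01 1.502004e-01 1.441961e-01 1.725747e-01 4.070301e-02
20.3245 3.310175e-01 1.283825e-01 1.220920e-01 1.719289e-01 3.699663e-02
21.4642 3.082579e-01 1.099640e-01 1.033762e-01 1.712539e-01 3.362775e-02
22.6678 2.886438e-01 9.442557e-02 8.752947e-02 1.705487e-01 3.056564e-02
23.9388 2.717066e-01 8.132767e-02 7.411190e-02 1.698123e-01 2.778237e-02
25.2811 2.570475e-01 7.029796e-02 6.275113e-02 1.690438e-01 2.525253e-02
26.6987 2.443272e-01 6.102122e-02 5.313188e-02 1.682423e-01 2.295306e-02
28.1958 2.332570e-01 5.323052e-02 4.498718e-02 1.674068e-01 2.086298e-02
29.7768 2.235908e-01 4.669981e-02 3.809100e-02 1.665366e-01 1.896321e-02
31.4465 2.151191e-01 4.123764e-02 3.225195e-02 1.656307e-01 1.723644e-02
33.2098 2.076632e-01 3.668187e-02 2.730798e-02 1.646883e-01 1.566691e-02
35.0719 2.010708e-01 3.289513e-02 2.312188e-02 1.637087e-01 1.424029e-02
37.0385 1.952122e-01 2.976104e-02 1.957748e-02 1.626911e-01 1.294359e-02
39.1154 1.899764e-01 2.718097e-02 1.657641e-02 1.616350e-01 1.176496e-02
41.3087 1.852688e-01 2.507131e-02 1.403538e-02 1.605398e-01 1.069365e-02
43.6250 1.810086e-01 2.336116e-02 1.188386e-02 1.594049e-01 9.719897e-03
46.0712 1.771268e-01 2.199035e-02 1.006216e-02 1.582299e-01 8.834813e-03
48.6545 1.735645e-01 2.090781e-02 8.519711e-03 1.570145e-01 8.030323e-03
51.3827 1.702713e-01 2.007016e-02 7.213706e-03 1.557585e-01 7.299090e-03
54.2639 1.672040e-01 1.944050e-02 6.107902e-03 1.544617e-01 6.634442e-03
57.3066 1.643261e-01 1.898743e-02 5.171609e-03 1.531242e-01 6.030316e-03
60.5200 1.616060e-01 1.868417e-02 4.378842e-03 1.517460e-01 5.481201e-03
63.9135 1.590171e-01 1.850788e-02 3.707600e-03 1.503274e-01 4.982088e-03
67.4973 1.565364e-01 1.843901e-02 3.139254e-03 1.488688e-01 4.528424e-03
71.2821 1.541447e-01 1.846084e-02 2.658031e-03 1.473706e-01 4.116070e-03
75.2791 1.518253e-01 1.855897e-02 2.250576e-03 1.458335e-01 3.741265e-03
79.5002 1.495644e-01 1.872103e-02 1.905581e-03 1.442583e-01 3.400589e-03
83.9580 1.473503e-01 1.893631e-02 1.613470e-03 1.426459e-01 3.090935e-03
88.6658 1.451729e-01 1.919556e-02 1.366138e-03 1.409973e-01 2.809477e-03
93.6375 1.430242e-01 1.949072e-02 1.156720e-03 1.393139e-01 2.553649e-03
98.8880 1.408973e-01 1.981477e-02 9.794038e-04 1.375968e-01 2.321116e-03
104.4330 1.387867e-01 2.016156e-02 8.292689e-04 1.358477e-01 2.109757e-03
110.2888 1.366878e-01 2.052569e-02 7.021485e-04 1.340680e-01 1.917645e-03
116.4730 1.345971e-01 2.090241e-02 5.945147e-04 1.322596e-01 1.743026e-03
123.0040 1.325119e-01 2.128751e-02 5.033803e-04 1.304242e-01 1.584308e-03
129.9012 1.304301e-01 2.167726e-02 4.262161e-04 1.285638e-01 1.440042e-03
137.1852 1.283502e-01 2.206835e-02 3.608805e-04 1.266805e-01 1.308913e-03
144.8775 1.262715e-01 2.245785e-02 3.055604e-04 1.247762e-01 1.189725e-03
153.0012 1.241933e-01 2.284314e-02 2.587204e-04 1.228532e-01 1.081390e-03
161.5805 1.221157e-01 2.322187e-02 2.190606e-04 1.209137e-01 9.829195e-04
170.6407 1.200387e-01 2.359199e-02 1.854803e-04 1.189598e-01 8.934158e-04
180.2091 1.179631e-01 2.395164e-02 1.570477e-04 1.169940e-01 8.120622e-04
190.3139 1.158894e-01 2.429920e-02 1.329735e-04 1.150183e-01 7.381166e-04
200.9854 1.138185e-01 2.463322e-02 1.125897e-04 1.130351e-01 6.709044e-04
212.2552 1.117516e-01 2.495244e-02 9.533060e-05 1.110464e-01 6.098125e-04
224.1570 1.096896e-01 2.525575e-02 8.071717e-05 1.090546e-01 5.542836e-04
236.7261 1.076338e-01 2.554218e-02 6.834386e-05 1.070617e-01 5.038110e-04
250.0000 1.055854e-01 2.581091e-02 5.786729e-05 1.050696e-01 4.579345e-04
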