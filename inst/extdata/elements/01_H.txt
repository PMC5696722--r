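# element: H  Z: 1  A: 1.0080
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 4.211514e-01 2.113198e-02 1.395232e-02 3.826419e-01 2.455719e-02
10.5607 4.159889e-01 1.936278e-02 1.181354e-02 3.818543e-01 2.232104e-02
11.1529 4.113183e-01 1.793864e-02 1.000262e-02 3.810271e-01 2.028851e-02
11.7783 4.070691e-01 1.680990e-02 8.469296e-03 3.801587e-01 1.844105e-02
12.4387 4.031801e-01 1.593460e-02 7.171020e-03 3.792473e-01 1.676183e-02
13.1362 3.995983e-01 1.527732e-02 6.071759e-03 3.782910e-01 1.523551e-02
13.8728 3.962772e-01 1.480814e-02 5.141006e-03 3.772880e-01 1.384818e-02
14.6507 3.931764e-01 1.450181e-02 4.352931e-03 3.762363e-01 1.258718e-02
15.4722 3.902608e-01 1.433703e-02 3.685661e-03 3.751341e-01 1.144100e-02
16.3397 3.874992e-01 1.429583e-02 3.120678e-03 3.739793e-01 1.039920e-02
17.2560 3.848646e-01 1.436307e-02 2.642303e-03 3.727700e-01 9.452256e-03
18.2235 3.823329e-01 1.452596e-02 2.237259e-03 3.715041e-01 8.591543e-03
19.2454 3.798831e-01 1.477373e-02 1.894304e-03 3.701796e-01 7.809205e-03
20.3245 3.774964e-01 1.509729e-02 1.603923e-03 3.687944e-01 7.098107e-03
21.4642 3.751563e-01 1.548897e-02 1.358054e-03 3.673464e-01 6.451760e-03
22.6678 3.728479e-01 1.594228e-02 1.149875e-03 3.658337e-01 5.864269e-03
23.9388 3.705580e-01 1.645172e-02 9.736082e-04 3.642541e-01 5.330274e-03
25.2811 3.682750e-01 1.701261e-02 8.243617e-04 3.626057e-01 4.844905e-03
26.6987 3.659881e-01 1.762095e-02 6.979936e-04 3.608864e-01 4.403732e-03
28.1958 3.636881e-01 1.827329e-02 5.909967e-04 3.590943e-01 4.002733e-03
29.7768 3.613662e-01 1.896663e-02 5.004016e-04 3.572276e-01 3.638248e-03
31.4465 3.590150e-01 1.969836e-02 4.236940e-04 3.552843e-01 3.306952e-03
33.2098 3.566275e-01 2.046611e-02 3.587450e-04 3.532629e-01 3.005824e-03
35.0719 3.541975e-01 2.126775e-02 3.037522e-04 3.511616e-01 2.732117e-03
37.0385 3.517195e-01 2.210133e-02 2.571894e-04 3.489789e-01 2.483333e-03
39.1154 3.491885e-01 2.296498e-02 2.177643e-04 3.467135e-01 2.257203e-03
41.3087 3.466002e-01 2.385691e-02 1.843828e-04 3.443642e-01 2.051664e-03
43.6250 3.439507e-01 2.477537e-02 1.561183e-04 3.419297e-01 1.864842e-03
46.0712 3.412366e-01 2.571863e-02 1.321866e-04 3.394093e-01 1.695031e-03
48.6545 3.384549e-01 2.668490e-02 1.119235e-04 3.368023e-01 1.540683e-03
51.3827 3.356032e-01 2.767237e-02 9.476648e-05 3.341081e-01 1.400390e-03
54.2639 3.326796e-01 2.867919e-02 8.023953e-05 3.313265e-01 1.272872e-03
57.3066 3.296823e-01 2.970341e-02 6.793944e-05 3.284574e-01 1.156965e-03
60.5200 3.266103e-01 3.074301e-02 5.752486e-05 3.255012e-01 1.051613e-03
63.9135 3.234628e-01 3.179589e-02 4.870676e-05 3.224582e-01 9.558544e-04
67.4973 3.202395e-01 3.285983e-02 4.124039e-05 3.193294e-01 8.688152e-04
71.2821 3.169404e-01 3.393257e-02 3.491857e-05 3.161157e-01 7.897018e-04
75.2791 3.135660e-01 3.501172e-02 2.956583e-05 3.128186e-01 7.177923e-04
79.5002 3.101172e-01 3.609483e-02 2.503362e-05 3.094397e-01 6.524308e-04
83.9580 3.065953e-01 3.717938e-02 2.119616e-05 3.059811e-01 5.930211e-04
88.6658 3.030018e-01 3.826277e-02 1.794696e-05 3.024449e-01 5.390212e-04
93.6375 2.993389e-01 3.934236e-02 1.519583e-05 2.988338e-01 4.899384e-04
98.8880 2.956088e-01 4.041548e-02 1.286643e-05 2.951506e-01 4.453251e-04
104.4330 2.918143e-01 4.147943e-02 1.089411e-05 2.913986e-01 4.047742e-04
110.2888 2.879583e-01 4.253151e-02 9.224127e-06 2.875812e-01 3.679159e-04
116.4730 2.840443e-01 4.356905e-02 7.810142e-06 2.837020e-01 3.344138e-04
123.0040 2.800757e-01 4.458939e-02 6.612909e-06 2.797651e-01 3.039624e-04
129.9012 2.760564e-01 4.558992e-02 5.599202e-06 2.757745e-01 2.762839e-04
137.1852 2.719905e-01 4.656813e-02 4.740888e-06 2.717346e-01 2.511257e-04
144.8775 2.678822e-01 4.752156e-02 4.014148e-06 2.676499e-01 2.282585e-04
153.0012 2.637359e-01 4.844786e-02 3.398811e-06 2.635250e-01 2.074735e-04
161.5805 2.595561e-01 4.934482e-02 2.877800e-06 2.593646e-01 1.885811e-04
170.6407 2.553474e-01 5.021032e-02 2.436656e-06 2.551736e-01 1.714091e-04
180.2091 2.511146e-01 5.104241e-02 2.063136e-06 2.509567e-01 1.558008e-04
190.3139 2.468622e-01 5.183926e-02 1.746873e-06 2.467188e-01 1.416137e-04
200.9854 2.425949e-01 5.259920e-02 1.479091e-06 2.424647e-01 1.287185e-04
212.2552 2.383173e-01 5.332074e-02 1.252358e-06 2.381990e-01 1.169975e-04
224.1570 2.340339e-01 5.400250e-02 1.060382e-06 2.339265e-01 1.063438e-04
236.7261 2.297491e-01 5.464330e-02 8.978336e-07 2.296515e-01 9.666027e-05
250.0000 2.254671e-01 5.524206e-02 7.602028e-07 2.253785e-01 8.785848e-05
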