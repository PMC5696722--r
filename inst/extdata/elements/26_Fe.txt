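# element: Fe  Z: 26  A: 55.8450
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 1.993597e+02 1.976556e+02 1.976522e+02 1.795734e-01 1.527877e+00
10.5607 1.689216e+02 1.673572e+02 1.673537e+02 1.792038e-01 1.388750e+00
11.1529 1.431408e+02 1.417034e+02 1.416997e+02 1.788156e-01 1.262292e+00
11.7783 1.213040e+02 1.199822e+02 1.199782e+02 1.784081e-01 1.147348e+00
12.4387 1.028074e+02 1.015906e+02 1.015865e+02 1.779804e-01 1.042872e+00
13.1362 8.713955e+01 8.601843e+01 8.601411e+01 1.775316e-01 9.479091e-01
13.8728 7.386748e+01 7.283337e+01 7.282883e+01 1.770609e-01 8.615934e-01
14.6507 6.262445e+01 6.166951e+01 6.166474e+01 1.765673e-01 7.831376e-01
15.4722 5.309990e+01 5.221703e+01 5.221203e+01 1.760500e-01 7.118258e-01
16.3397 4.503085e+01 4.421358e+01 4.420834e+01 1.755081e-01 6.470076e-01
17.2560 3.819458e+01 3.743705e+01 3.743155e+01 1.749406e-01 5.880918e-01
18.2235 3.240247e+01 3.169935e+01 3.169359e+01 1.743465e-01 5.345407e-01
19.2454 2.749480e+01 2.684125e+01 2.683521e+01 1.737249e-01 4.858659e-01
20.3245 2.333628e+01 2.272792e+01 2.272158e+01 1.730748e-01 4.416234e-01
21.4642 1.981235e+01 1.924518e+01 1.923854e+01 1.723953e-01 4.014096e-01
22.6678 1.682597e+01 1.629637e+01 1.628943e+01 1.716854e-01 3.648577e-01
23.9388 1.429496e+01 1.379965e+01 1.379239e+01 1.709441e-01 3.316341e-01
25.2811 1.214973e+01 1.168572e+01 1.167812e+01 1.701705e-01 3.014358e-01
26.6987 1.033131e+01 9.895901e+00 9.887959e+00 1.693636e-01 2.739873e-01
28.1958 8.789774e+00 8.380511e+00 8.372213e+00 1.685226e-01 2.490383e-01
29.7768 7.482826e+00 7.097485e+00 7.088819e+00 1.676465e-01 2.263611e-01
31.4465 6.374642e+00 6.011204e+00 6.002159e+00 1.667346e-01 2.057489e-01
33.2098 5.434875e+00 5.091512e+00 5.082075e+00 1.657859e-01 1.870136e-01
35.0719 4.637817e+00 4.312872e+00 4.303033e+00 1.647998e-01 1.699843e-01
37.0385 3.961693e+00 3.653664e+00 3.643412e+00 1.637755e-01 1.545057e-01
39.1154 3.388055e+00 3.095581e+00 3.084906e+00 1.627123e-01 1.404366e-01
41.3087 2.901272e+00 2.623124e+00 2.612014e+00 1.616097e-01 1.276486e-01
43.6250 2.488105e+00 2.223167e+00 2.211613e+00 1.604673e-01 1.160250e-01
46.0712 2.137335e+00 1.884598e+00 1.872590e+00 1.592844e-01 1.054599e-01
48.6545 1.839455e+00 1.598008e+00 1.585537e+00 1.580610e-01 9.585681e-02
51.3827 1.586411e+00 1.355429e+00 1.342487e+00 1.567966e-01 8.712818e-02
54.2639 1.371380e+00 1.150115e+00 1.136694e+00 1.554912e-01 7.919437e-02
57.3066 1.188576e+00 9.763557e-01 9.624478e-01 1.541447e-01 7.198301e-02
60.5200 1.033098e+00 8.293128e-01 8.149121e-01 1.527574e-01 6.542831e-02
63.9135 9.007923e-01 7.048915e-01 6.899926e-01 1.513293e-01 5.947047e-02
67.4973 7.881382e-01 5.996239e-01 5.842221e-01 1.498610e-01 5.405514e-02
71.2821 6.921512e-01 5.105736e-01 4.946655e-01 1.483528e-01 4.913293e-02
75.2791 6.103016e-01 4.352543e-01 4.188372e-01 1.468055e-01 4.465894e-02
79.5002 5.404448e-01 3.715603e-01 3.546328e-01 1.452197e-01 4.059234e-02
83.9580 4.807630e-01 3.177086e-01 3.002704e-01 1.435966e-01 3.689604e-02
88.6658 4.297147e-01 2.721895e-01 2.542413e-01 1.419371e-01 3.353632e-02
93.6375 3.859930e-01 2.337243e-01 2.152681e-01 1.402424e-01 3.048254e-02
98.8880 3.484899e-01 2.012301e-01 1.822692e-01 1.385139e-01 2.770683e-02
104.4330 3.162657e-01 1.737899e-01 1.543288e-01 1.367531e-01 2.518387e-02
110.2888 2.885236e-01 1.506271e-01 1.306714e-01 1.349616e-01 2.289065e-02
116.4730 2.645878e-01 1.310837e-01 1.106405e-01 1.331411e-01 2.080625e-02
123.0040 2.438853e-01 1.146028e-01 9.368018e-02 1.312935e-01 1.891165e-02
129.9012 2.259300e-01 1.007124e-01 7.931975e-02 1.294207e-01 1.718958e-02
137.1852 2.103097e-01 8.901281e-02 6.716066e-02 1.275248e-01 1.562431e-02
144.8775 1.966748e-01 7.916539e-02 5.686546e-02 1.256078e-01 1.420158e-02
153.0012 1.847288e-01 7.088337e-02 4.814843e-02 1.236720e-01 1.290839e-02
161.5805 1.742202e-01 6.392378e-02 4.076766e-02 1.217195e-01 1.173297e-02
170.6407 1.649356e-01 5.808081e-02 3.451830e-02 1.197527e-01 1.066457e-02
180.2091 1.566941e-01 5.318010e-02 2.922692e-02 1.177737e-01 9.693469e-03
190.3139 1.493423e-01 4.907395e-02 2.474666e-02 1.157849e-01 8.810791e-03
200.9854 1.427501e-01 4.563725e-02 2.095319e-02 1.137884e-01 8.008489e-03
212.2552 1.368070e-01 4.276401e-02 1.774123e-02 1.117865e-01 7.279244e-03
224.1570 1.314195e-01 4.036446e-02 1.502164e-02 1.097814e-01 6.616403e-03
236.7261 1.265081e-01 3.836256e-02 1.271894e-02 1.077752e-01 6.013920e-03
250.0000 1.220054e-01 3.669392e-02 1.076923e-02 1.057699e-01 5.466298e-03
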