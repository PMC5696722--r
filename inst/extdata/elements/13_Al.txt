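# element: Al  Z: 13  A: 26.9820
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 2.353362e+01 2.279226e+01 2.278877e+01 1.858328e-01 5.590150e-01
10.5607 1.998899e+01 1.929910e+01 1.929543e+01 1.854502e-01 5.081117e-01
11.1529 1.698449e+01 1.634145e+01 1.633759e+01 1.850485e-01 4.618435e-01
11.7783 1.443758e+01 1.383722e+01 1.383317e+01 1.846268e-01 4.197885e-01
12.4387 1.227840e+01 1.171691e+01 1.171265e+01 1.841841e-01 3.815629e-01
13.1362 1.044773e+01 9.921667e+00 9.917196e+00 1.837197e-01 3.468182e-01
13.8728 8.895438e+00 8.401663e+00 8.396969e+00 1.832326e-01 3.152373e-01
14.6507 7.579033e+00 7.114708e+00 7.109780e+00 1.827218e-01 2.865321e-01
15.4722 6.462534e+00 6.025079e+00 6.019906e+00 1.821865e-01 2.604407e-01
16.3397 5.515453e+00 5.102530e+00 5.097102e+00 1.816257e-01 2.367252e-01
17.2560 4.711964e+00 4.321449e+00 4.315757e+00 1.810384e-01 2.151693e-01
18.2235 4.030185e+00 3.660153e+00 3.654185e+00 1.804236e-01 1.955762e-01
19.2454 3.451575e+00 3.100283e+00 3.094028e+00 1.797803e-01 1.777672e-01
20.3245 2.960425e+00 2.626291e+00 2.619738e+00 1.791076e-01 1.615799e-01
21.4642 2.543423e+00 2.225015e+00 2.218153e+00 1.784044e-01 1.468666e-01
22.6678 2.189290e+00 1.885311e+00 1.878127e+00 1.776697e-01 1.334930e-01
23.9388 1.888465e+00 1.597742e+00 1.590225e+00 1.769026e-01 1.213373e-01
25.2811 1.632847e+00 1.354318e+00 1.346456e+00 1.761020e-01 1.102884e-01
26.6987 1.415568e+00 1.148274e+00 1.140055e+00 1.752670e-01 1.002457e-01
28.1958 1.230808e+00 9.738812e-01 9.652937e-01 1.743967e-01 9.111741e-02
29.7768 1.073632e+00 8.262900e-01 8.173218e-01 1.734901e-01 8.282034e-02
31.4465 9.398580e-01 7.013937e-01 6.920328e-01 1.725464e-01 7.527880e-02
33.2098 8.259382e-01 5.957149e-01 5.859496e-01 1.715646e-01 6.842399e-02
35.0719 7.288657e-01 5.063095e-01 4.961282e-01 1.705441e-01 6.219337e-02
37.0385 6.460898e-01 4.306844e-01 4.200756e-01 1.694841e-01 5.653010e-02
39.1154 5.754478e-01 3.667287e-01 3.556814e-01 1.683839e-01 5.138252e-02
41.3087 5.151048e-01 3.126549e-01 3.011582e-01 1.672429e-01 4.670368e-02
43.6250 4.635045e-01 2.669496e-01 2.549930e-01 1.660606e-01 4.245089e-02
46.0712 4.193265e-01 2.283309e-01 2.159046e-01 1.648366e-01 3.858535e-02
48.6545 3.814504e-01 1.957135e-01 1.828081e-01 1.635704e-01 3.507181e-02
51.3827 3.489253e-01 1.681784e-01 1.547851e-01 1.622620e-01 3.187820e-02
54.2639 3.209442e-01 1.449471e-01 1.310578e-01 1.609110e-01 2.897540e-02
57.3066 2.968223e-01 1.253603e-01 1.109676e-01 1.595177e-01 2.633693e-02
60.5200 2.759779e-01 1.088598e-01 9.395718e-02 1.580820e-01 2.393872e-02
63.9135 2.579173e-01 9.497253e-02 7.955429e-02 1.566041e-01 2.175888e-02
67.4973 2.422214e-01 8.329783e-02 6.735924e-02 1.550846e-01 1.977754e-02
71.2821 2.285341e-01 7.349624e-02 5.703360e-02 1.535239e-01 1.797661e-02
75.2791 2.165531e-01 6.528014e-02 4.829080e-02 1.519226e-01 1.633968e-02
79.5002 2.060216e-01 5.840576e-02 4.088820e-02 1.502816e-01 1.485180e-02
83.9580 1.967217e-01 5.266650e-02 3.462037e-02 1.486019e-01 1.349941e-02
88.6658 1.884680e-01 4.788721e-02 2.931334e-02 1.468845e-01 1.227017e-02
93.6375 1.811034e-01 4.391935e-02 2.481983e-02 1.451307e-01 1.115286e-02
98.8880 1.744944e-01 4.063696e-02 2.101515e-02 1.433420e-01 1.013729e-02
104.4330 1.685277e-01 3.793318e-02 1.779369e-02 1.415198e-01 9.214200e-03
110.2888 1.631071e-01 3.571731e-02 1.506606e-02 1.396658e-01 8.375164e-03
116.4730 1.581510e-01 3.391238e-02 1.275655e-02 1.377819e-01 7.612529e-03
123.0040 1.535903e-01 3.245301e-02 1.080107e-02 1.358699e-01 6.919340e-03
129.9012 1.493665e-01 3.128371e-02 9.145354e-03 1.339318e-01 6.289271e-03
137.1852 1.454299e-01 3.035728e-02 7.743443e-03 1.319698e-01 5.716576e-03
144.8775 1.417385e-01 2.963367e-02 6.556435e-03 1.299861e-01 5.196030e-03
153.0012 1.382571e-01 2.907878e-02 5.551385e-03 1.279828e-01 4.722885e-03
161.5805 1.349555e-01 2.866367e-02 4.700402e-03 1.259623e-01 4.292824e-03
170.6407 1.318087e-01 2.836368e-02 3.979867e-03 1.239269e-01 3.901923e-03
180.2091 1.287953e-01 2.815789e-02 3.369785e-03 1.218789e-01 3.546618e-03
190.3139 1.258976e-01 2.802848e-02 2.853223e-03 1.198207e-01 3.223666e-03
200.9854 1.231007e-01 2.796031e-02 2.415847e-03 1.177547e-01 2.930122e-03
212.2552 1.203919e-01 2.794050e-02 2.045517e-03 1.156830e-01 2.663308e-03
224.1570 1.177608e-01 2.795814e-02 1.731955e-03 1.136080e-01 2.420790e-03
236.7261 1.151987e-01 2.800393e-02 1.466460e-03 1.115319e-01 2.200355e-03
250.0000 1.126983e-01 2.807000e-02 1.241663e-03 1.094567e-01 1.999993e-03
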