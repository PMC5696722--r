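# element: Mg  Z: 12  A: 24.3050
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 1.882357e+01 1.812867e+01 1.812510e+01 1.904314e-01 5.080386e-01
10.5607 1.599848e+01 1.535042e+01 1.534667e+01 1.900395e-01 4.617771e-01
11.1529 1.360350e+01 1.299809e+01 1.299414e+01 1.896278e-01 4.197281e-01
11.7783 1.157295e+01 1.100639e+01 1.100224e+01 1.891956e-01 3.815081e-01
12.4387 9.851197e+00 9.320048e+00 9.315687e+00 1.887420e-01 3.467683e-01
13.1362 8.391124e+00 7.892247e+00 7.887666e+00 1.882661e-01 3.151919e-01
13.8728 7.152807e+00 6.683360e+00 6.678549e+00 1.877669e-01 2.864909e-01
14.6507 6.102427e+00 5.659831e+00 5.654780e+00 1.872436e-01 2.604033e-01
15.4722 5.211333e+00 4.793248e+00 4.787947e+00 1.866950e-01 2.366912e-01
16.3397 4.455251e+00 4.059554e+00 4.053992e+00 1.861203e-01 2.151383e-01
17.2560 3.813614e+00 3.438381e+00 3.432547e+00 1.855185e-01 1.955481e-01
18.2235 3.268995e+00 2.912481e+00 2.906365e+00 1.848884e-01 1.777416e-01
19.2454 2.806628e+00 2.467252e+00 2.460842e+00 1.842293e-01 1.615567e-01
20.3245 2.414000e+00 2.090330e+00 2.083614e+00 1.835399e-01 1.468455e-01
21.4642 2.080506e+00 1.771245e+00 1.764213e+00 1.828193e-01 1.334739e-01
22.6678 1.797159e+00 1.501135e+00 1.493773e+00 1.820664e-01 1.213199e-01
23.9388 1.556342e+00 1.272492e+00 1.264789e+00 1.812803e-01 1.102726e-01
25.2811 1.351598e+00 1.078964e+00 1.070907e+00 1.804599e-01 1.002313e-01
26.6987 1.177454e+00 9.151677e-01 9.067455e-01 1.796043e-01 9.110431e-02
28.1958 1.029269e+00 7.765486e-01 7.677486e-01 1.787124e-01 8.280844e-02
29.7768 9.031101e-01 6.592490e-01 6.500588e-01 1.777834e-01 7.526798e-02
31.4465 7.956403e-01 5.600024e-01 5.504099e-01 1.768163e-01 6.841415e-02
33.2098 7.040311e-01 4.760434e-01 4.660364e-01 1.758102e-01 6.218443e-02
35.0719 6.258832e-01 4.050300e-01 3.945967e-01 1.747645e-01 5.652197e-02
37.0385 5.591615e-01 3.449794e-01 3.341082e-01 1.736782e-01 5.137514e-02
39.1154 5.021398e-01 2.942127e-01 2.828920e-01 1.725508e-01 4.669697e-02
41.3087 4.533533e-01 2.513081e-01 2.395269e-01 1.713816e-01 4.244479e-02
43.6250 4.115591e-01 2.150617e-01 2.028093e-01 1.701700e-01 3.857980e-02
46.0712 3.757027e-01 1.844540e-01 1.717203e-01 1.689157e-01 3.506676e-02
48.6545 3.448887e-01 1.586216e-01 1.453969e-01 1.676182e-01 3.187362e-02
51.3827 3.183573e-01 1.368334e-01 1.231087e-01 1.662774e-01 2.897124e-02
54.2639 2.954633e-01 1.184701e-01 1.042371e-01 1.648930e-01 2.633315e-02
57.3066 2.756588e-01 1.030072e-01 8.825838e-02 1.634652e-01 2.393527e-02
60.5200 2.584787e-01 9.000048e-02 7.472907e-02 1.619939e-01 2.175575e-02
63.9135 2.435279e-01 7.907348e-02 6.327369e-02 1.604795e-01 1.977469e-02
67.4973 2.304707e-01 6.990734e-02 5.357433e-02 1.589224e-01 1.797403e-02
71.2821 2.190222e-01 6.223184e-02 4.536181e-02 1.573230e-01 1.633733e-02
75.2791 2.089400e-01 5.581796e-02 3.840820e-02 1.556821e-01 1.484967e-02
79.5002 2.000185e-01 5.047158e-02 3.252053e-02 1.540005e-01 1.349747e-02
83.9580 1.920830e-01 4.602810e-02 2.753539e-02 1.522792e-01 1.226841e-02
88.6658 1.849850e-01 4.234794e-02 2.331443e-02 1.505194e-01 1.115126e-02
93.6375 1.785986e-01 3.931267e-02 1.974051e-02 1.487222e-01 1.013583e-02
98.8880 1.728165e-01 3.682183e-02 1.671445e-02 1.468892e-01 9.212875e-03
104.4330 1.675481e-01 3.479012e-02 1.415226e-02 1.450219e-01 8.373960e-03
110.2888 1.627163e-01 3.314512e-02 1.198283e-02 1.431221e-01 7.611435e-03
116.4730 1.582558e-01 3.182531e-02 1.014595e-02 1.411915e-01 6.918345e-03
123.0040 1.541112e-01 3.077841e-02 8.590659e-03 1.392322e-01 6.288367e-03
129.9012 1.502357e-01 2.995998e-02 7.273779e-03 1.372462e-01 5.715755e-03
137.1852 1.465897e-01 2.933222e-02 6.158766e-03 1.352356e-01 5.195284e-03
144.8775 1.431396e-01 2.886299e-02 5.214676e-03 1.332028e-01 4.722206e-03
153.0012 1.398574e-01 2.852493e-02 4.415307e-03 1.311499e-01 4.292207e-03
161.5805 1.367192e-01 2.829475e-02 3.738476e-03 1.290794e-01 3.901362e-03
170.6407 1.337051e-01 2.815262e-02 3.165397e-03 1.269936e-01 3.546108e-03
180.2091 1.307983e-01 2.808169e-02 2.680166e-03 1.248950e-01 3.223203e-03
190.3139 1.279849e-01 2.806757e-02 2.269318e-03 1.227859e-01 2.929701e-03
200.9854 1.252531e-01 2.809804e-02 1.921450e-03 1.206687e-01 2.662925e-03
212.2552 1.225931e-01 2.816270e-02 1.626906e-03 1.185458e-01 2.420442e-03
224.1570 1.199970e-01 2.825270e-02 1.377515e-03 1.164194e-01 2.200039e-03
236.7261 1.174580e-01 2.836053e-02 1.166352e-03 1.142919e-01 1.999705e-03
250.0000 1.149705e-01 2.847980e-02 9.875598e-04 1.121653e-01 1.817614e-03
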