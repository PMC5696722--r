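# element: F  Z: 9  A: 18.9980
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 7.494110e+00 6.998198e+00 6.994770e+00 1.827207e-01 3.166195e-01
10.5607 6.392660e+00 5.926132e+00 5.922527e+00 1.823446e-01 2.877884e-01
11.1529 5.458182e+00 5.018440e+00 5.014650e+00 1.819496e-01 2.615827e-01
11.7783 4.665242e+00 4.249927e+00 4.245944e+00 1.815349e-01 2.377632e-01
12.4387 3.992287e+00 3.599259e+00 3.595074e+00 1.810997e-01 2.161127e-01
13.1362 3.421054e+00 3.048374e+00 3.043978e+00 1.806430e-01 1.964337e-01
13.8728 2.936071e+00 2.581976e+00 2.577360e+00 1.801640e-01 1.785466e-01
14.6507 2.524221e+00 2.187117e+00 2.182271e+00 1.796619e-01 1.622884e-01
15.4722 2.174392e+00 1.852832e+00 1.847746e+00 1.791355e-01 1.475105e-01
16.3397 1.877164e+00 1.569838e+00 1.564501e+00 1.785841e-01 1.340784e-01
17.2560 1.624551e+00 1.330272e+00 1.324676e+00 1.780066e-01 1.218693e-01
18.2235 1.409787e+00 1.127481e+00 1.121613e+00 1.774021e-01 1.107720e-01
19.2454 1.227134e+00 9.558290e-01 9.496788e-01 1.767696e-01 1.006852e-01
20.3245 1.071726e+00 8.105439e-01 8.041005e-01 1.761082e-01 9.151693e-02
21.4642 9.394385e-01 6.875861e-01 6.808382e-01 1.754167e-01 8.318349e-02
22.6678 8.267744e-01 5.835348e-01 5.764711e-01 1.746944e-01 7.560888e-02
23.9388 7.307667e-01 4.954938e-01 4.881026e-01 1.739401e-01 6.872401e-02
25.2811 6.488993e-01 4.210106e-01 4.132804e-01 1.731529e-01 6.246606e-02
26.6987 5.790376e-01 3.580089e-01 3.499278e-01 1.723319e-01 5.677797e-02
28.1958 5.193705e-01 3.047303e-01 2.962866e-01 1.714761e-01 5.160782e-02
29.7768 4.683614e-01 2.596863e-01 2.508682e-01 1.705847e-01 4.690846e-02
31.4465 4.247059e-01 2.216162e-01 2.124121e-01 1.696568e-01 4.263702e-02
33.2098 3.872970e-01 1.894527e-01 1.798510e-01 1.686915e-01 3.875454e-02
35.0719 3.551949e-01 1.622921e-01 1.522813e-01 1.676881e-01 3.522558e-02
37.0385 3.276015e-01 1.393688e-01 1.289377e-01 1.666458e-01 3.201798e-02
39.1154 3.038391e-01 1.200349e-01 1.091726e-01 1.655640e-01 2.910245e-02
41.3087 2.833319e-01 1.037415e-01 9.243730e-02 1.644421e-01 2.645241e-02
43.6250 2.655907e-01 9.002368e-02 7.826739e-02 1.632796e-01 2.404368e-02
46.0712 2.502000e-01 7.848776e-02 6.626962e-02 1.620761e-01 2.185428e-02
48.6545 2.368064e-01 6.880024e-02 5.611101e-02 1.608312e-01 1.986425e-02
51.3827 2.251097e-01 6.067860e-02 4.750964e-02 1.595446e-01 1.805544e-02
54.2639 2.148544e-01 5.388347e-02 4.022678e-02 1.582163e-01 1.641132e-02
57.3066 2.058235e-01 4.821198e-02 3.406034e-02 1.568463e-01 1.491693e-02
60.5200 1.978324e-01 4.349221e-02 2.883915e-02 1.554346e-01 1.355860e-02
63.9135 1.907238e-01 3.957838e-02 2.441834e-02 1.539815e-01 1.232397e-02
67.4973 1.843644e-01 3.634687e-02 2.067520e-02 1.524874e-01 1.120176e-02
71.2821 1.786404e-01 3.369280e-02 1.750586e-02 1.509528e-01 1.018174e-02
75.2791 1.734553e-01 3.152716e-02 1.482235e-02 1.493784e-01 9.254601e-03
79.5002 1.687270e-01 2.977439e-02 1.255020e-02 1.477649e-01 8.411886e-03
83.9580 1.643855e-01 2.837027e-02 1.062635e-02 1.461133e-01 7.645908e-03
88.6658 1.603718e-01 2.726023e-02 8.997416e-03 1.444247e-01 6.949679e-03
93.6375 1.566353e-01 2.639785e-02 7.618183e-03 1.427003e-01 6.316848e-03
98.8880 1.531335e-01 2.574359e-02 6.450376e-03 1.409415e-01 5.741642e-03
104.4330 1.498302e-01 2.526380e-02 5.461584e-03 1.391498e-01 5.218813e-03
110.2888 1.466949e-01 2.492978e-02 4.624366e-03 1.373269e-01 4.743593e-03
116.4730 1.437017e-01 2.471702e-02 3.915488e-03 1.354745e-01 4.311646e-03
123.0040 1.408288e-01 2.460462e-02 3.315274e-03 1.335945e-01 3.919032e-03
129.9012 1.380582e-01 2.457468e-02 2.807069e-03 1.316889e-01 3.562169e-03
137.1852 1.353743e-01 2.461190e-02 2.376767e-03 1.297598e-01 3.237801e-03
144.8775 1.327646e-01 2.470319e-02 2.012428e-03 1.278092e-01 2.942970e-03
153.0012 1.302184e-01 2.483733e-02 1.703938e-03 1.258395e-01 2.674986e-03
161.5805 1.277270e-01 2.500470e-02 1.442738e-03 1.238528e-01 2.431404e-03
170.6407 1.252831e-01 2.519705e-02 1.221578e-03 1.218515e-01 2.210003e-03
180.2091 1.228809e-01 2.540731e-02 1.034320e-03 1.198378e-01 2.008762e-03
190.3139 1.205158e-01 2.562942e-02 8.757665e-04 1.178141e-01 1.825846e-03
200.9854 1.181838e-01 2.585819e-02 7.415184e-04 1.157827e-01 1.659587e-03
212.2552 1.158821e-01 2.608918e-02 6.278495e-04 1.137457e-01 1.508466e-03
224.1570 1.136082e-01 2.631859e-02 5.316051e-04 1.117055e-01 1.371107e-03
236.7261 1.113605e-01 2.654317e-02 4.501143e-04 1.096641e-01 1.246255e-03
250.0000 1.091375e-01 2.676016e-02 3.811153e-04 1.076236e-01 1.132772e-03
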