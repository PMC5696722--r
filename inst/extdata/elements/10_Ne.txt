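# element: Ne  Z: 10  A: 20.1800
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 1.079279e+01 1.021735e+01 1.021376e+01 1.911313e-01 3.878985e-01
10.5607 9.191390e+00 8.651846e+00 8.648075e+00 1.907379e-01 3.525768e-01
11.1529 7.833190e+00 7.326357e+00 7.322393e+00 1.903248e-01 3.204715e-01
11.7783 6.681109e+00 6.204094e+00 6.199928e+00 1.898910e-01 2.912897e-01
12.4387 5.703729e+00 5.253906e+00 5.249528e+00 1.894357e-01 2.647651e-01
13.1362 4.874431e+00 4.449415e+00 4.444817e+00 1.889580e-01 2.406559e-01
13.8728 4.170661e+00 3.768290e+00 3.763462e+00 1.884570e-01 2.187420e-01
14.6507 3.573308e+00 3.191622e+00 3.186553e+00 1.879317e-01 1.988235e-01
15.4722 3.066179e+00 2.703400e+00 2.698079e+00 1.873812e-01 1.807189e-01
16.3397 2.635552e+00 2.290067e+00 2.284485e+00 1.868043e-01 1.642628e-01
17.2560 2.269797e+00 1.940146e+00 1.934292e+00 1.862003e-01 1.493052e-01
18.2235 1.959057e+00 1.643918e+00 1.637780e+00 1.855680e-01 1.357096e-01
19.2454 1.694980e+00 1.393155e+00 1.386721e+00 1.849064e-01 1.233520e-01
20.3245 1.470482e+00 1.180888e+00 1.174148e+00 1.842144e-01 1.121197e-01
21.4642 1.279562e+00 1.001219e+00 9.941602e-01 1.834912e-01 1.019102e-01
22.6678 1.117129e+00 8.491522e-01 8.417633e-01 1.827356e-01 9.263034e-02
23.9388 9.788697e-01 7.204590e-01 7.127276e-01 1.819466e-01 8.419551e-02
25.2811 8.611240e-01 6.115582e-01 6.034721e-01 1.811232e-01 7.652875e-02
26.6987 7.607891e-01 5.194177e-01 5.109646e-01 1.802644e-01 6.956011e-02
28.1958 6.752330e-01 4.414701e-01 4.326378e-01 1.793692e-01 6.322604e-02
29.7768 6.022233e-01 3.755418e-01 3.663178e-01 1.784368e-01 5.746873e-02
31.4465 5.398660e-01 3.197920e-01 3.101642e-01 1.774661e-01 5.223569e-02
33.2098 4.865540e-01 2.726622e-01 2.626185e-01 1.764564e-01 4.747916e-02
35.0719 4.409237e-01 2.328327e-01 2.223611e-01 1.754068e-01 4.315575e-02
37.0385 4.018175e-01 1.991862e-01 1.882749e-01 1.743165e-01 3.922603e-02
39.1154 3.682530e-01 1.707762e-01 1.594139e-01 1.731850e-01 3.565414e-02
41.3087 3.393959e-01 1.468015e-01 1.349770e-01 1.720114e-01 3.240751e-02
43.6250 3.145380e-01 1.265835e-01 1.142861e-01 1.707954e-01 2.945652e-02
46.0712 2.930776e-01 1.095475e-01 9.676692e-02 1.695365e-01 2.677423e-02
48.6545 2.745038e-01 9.520663e-02 8.193331e-02 1.682342e-01 2.433620e-02
51.3827 2.583822e-01 8.314872e-02 6.937358e-02 1.668885e-01 2.212017e-02
54.2639 2.443441e-01 7.302447e-02 5.873916e-02 1.654990e-01 2.010593e-02
57.3066 2.320760e-01 6.453796e-02 4.973491e-02 1.640659e-01 1.827510e-02
60.5200 2.213112e-01 5.743848e-02 4.211094e-02 1.625893e-01 1.661099e-02
63.9135 2.118234e-01 5.151352e-02 3.565567e-02 1.610693e-01 1.509841e-02
67.4973 2.034200e-01 4.658297e-02 3.018993e-02 1.595065e-01 1.372356e-02
71.2821 1.959372e-01 4.249408e-02 2.556206e-02 1.579012e-01 1.247391e-02
75.2791 1.892359e-01 3.911734e-02 2.164359e-02 1.562543e-01 1.133804e-02
79.5002 1.831979e-01 3.634283e-02 1.832580e-02 1.545665e-01 1.030561e-02
83.9580 1.777227e-01 3.407728e-02 1.551660e-02 1.528389e-01 9.367194e-03
88.6658 1.727248e-01 3.224149e-02 1.313803e-02 1.510726e-01 8.514226e-03
93.6375 1.681318e-01 3.076817e-02 1.112407e-02 1.492688e-01 7.738929e-03
98.8880 1.638821e-01 2.960012e-02 9.418841e-03 1.474291e-01 7.034230e-03
104.4330 1.599236e-01 2.868872e-02 7.975007e-03 1.455549e-01 6.393699e-03
110.2888 1.562121e-01 2.799257e-02 6.752501e-03 1.436481e-01 5.811495e-03
116.4730 1.527101e-01 2.747643e-02 5.717396e-03 1.417104e-01 5.282306e-03
123.0040 1.493862e-01 2.711026e-02 4.840964e-03 1.397439e-01 4.801304e-03
129.9012 1.462136e-01 2.686846e-02 4.098883e-03 1.377506e-01 4.364102e-03
137.1852 1.431699e-01 2.672918e-02 3.470556e-03 1.357326e-01 3.966711e-03
144.8775 1.402364e-01 2.667377e-02 2.938547e-03 1.336923e-01 3.605506e-03
153.0012 1.373972e-01 2.668632e-02 2.488091e-03 1.316319e-01 3.277193e-03
161.5805 1.346392e-01 2.675321e-02 2.106687e-03 1.295538e-01 2.978775e-03
170.6407 1.319516e-01 2.686281e-02 1.783748e-03 1.274603e-01 2.707530e-03
180.2091 1.293253e-01 2.700519e-02 1.510314e-03 1.253540e-01 2.460985e-03
190.3139 1.267528e-01 2.717186e-02 1.278795e-03 1.232371e-01 2.236890e-03
200.9854 1.242282e-01 2.735556e-02 1.082765e-03 1.211122e-01 2.033201e-03
212.2552 1.217463e-01 2.755011e-02 9.167860e-04 1.189815e-01 1.848060e-03
224.1570 1.193033e-01 2.775021e-02 7.762500e-04 1.168473e-01 1.679777e-03
236.7261 1.168960e-01 2.795138e-02 6.572570e-04 1.147119e-01 1.526818e-03
250.0000 1.145218e-01 2.814978e-02 5.565047e-04 1.125775e-01 1.387788e-03
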