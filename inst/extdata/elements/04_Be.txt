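# element: Be  Z: 4  A: 9.0120
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 7.619750e-01 5.060961e-01 5.028839e-01 1.711953e-01 8.789578e-02
10.5607 6.765308e-01 4.291733e-01 4.257958e-01 1.708429e-01 7.989208e-02
11.1529 6.036147e-01 3.640753e-01 3.605246e-01 1.704729e-01 7.261718e-02
11.7783 5.413481e-01 3.089907e-01 3.052591e-01 1.700843e-01 6.600473e-02
12.4387 4.881362e-01 2.623861e-01 2.584653e-01 1.696766e-01 5.999440e-02
13.1362 4.426247e-01 2.229632e-01 2.188446e-01 1.692487e-01 5.453137e-02
13.8728 4.036632e-01 1.896225e-01 1.852974e-01 1.687999e-01 4.956580e-02
14.6507 3.702746e-01 1.614334e-01 1.568928e-01 1.683294e-01 4.505238e-02
15.4722 3.416286e-01 1.376078e-01 1.328424e-01 1.678363e-01 4.094996e-02
16.3397 3.170194e-01 1.174785e-01 1.124787e-01 1.673196e-01 3.722109e-02
17.2560 2.958470e-01 1.004805e-01 9.523659e-02 1.667786e-01 3.383178e-02
18.2235 2.776009e-01 8.613558e-02 8.063757e-02 1.662122e-01 3.075109e-02
19.2454 2.618470e-01 7.403877e-02 6.827647e-02 1.656196e-01 2.795092e-02
20.3245 2.482159e-01 6.384720e-02 5.781023e-02 1.649999e-01 2.540574e-02
21.4642 2.363928e-01 5.527060e-02 4.894837e-02 1.643521e-01 2.309232e-02
22.6678 2.261098e-01 4.806315e-02 4.144498e-02 1.636753e-01 2.098955e-02
23.9388 2.171386e-01 4.201675e-02 3.509179e-02 1.629686e-01 1.907826e-02
25.2811 2.092846e-01 3.695517e-02 2.971249e-02 1.622310e-01 1.734102e-02
26.6987 2.023816e-01 3.272919e-02 2.515780e-02 1.614618e-01 1.576196e-02
28.1958 1.962880e-01 2.921243e-02 2.130131e-02 1.606600e-01 1.432669e-02
29.7768 1.908830e-01 2.629784e-02 1.803599e-02 1.598249e-01 1.302212e-02
31.4465 1.860630e-01 2.389476e-02 1.527121e-02 1.589554e-01 1.183634e-02
33.2098 1.817398e-01 2.192636e-02 1.293026e-02 1.580510e-01 1.075853e-02
35.0719 1.778379e-01 2.032752e-02 1.094815e-02 1.571109e-01 9.778869e-03
37.0385 1.742927e-01 1.904303e-02 9.269886e-03 1.561344e-01 8.888414e-03
39.1154 1.710488e-01 1.802607e-02 7.848885e-03 1.551208e-01 8.079044e-03
41.3087 1.680588e-01 1.723688e-02 6.645713e-03 1.540697e-01 7.343374e-03
43.6250 1.652822e-01 1.664172e-02 5.626978e-03 1.529805e-01 6.674694e-03
46.0712 1.626842e-01 1.621187e-02 4.764407e-03 1.518529e-01 6.066902e-03
48.6545 1.602350e-01 1.592290e-02 4.034061e-03 1.506865e-01 5.514456e-03
51.3827 1.579091e-01 1.575399e-02 3.415671e-03 1.494811e-01 5.012315e-03
54.2639 1.556846e-01 1.568735e-02 2.892076e-03 1.482366e-01 4.555898e-03
57.3066 1.535428e-01 1.570776e-02 2.448743e-03 1.469530e-01 4.141043e-03
60.5200 1.514677e-01 1.580216e-02 2.073370e-03 1.456303e-01 3.763963e-03
63.9135 1.494457e-01 1.595934e-02 1.755539e-03 1.442689e-01 3.421221e-03
67.4973 1.474652e-01 1.616958e-02 1.486429e-03 1.428691e-01 3.109688e-03
71.2821 1.455164e-01 1.642450e-02 1.258571e-03 1.414313e-01 2.826522e-03
75.2791 1.435909e-01 1.671678e-02 1.065642e-03 1.399561e-01 2.569142e-03
79.5002 1.416819e-01 1.704004e-02 9.022874e-04 1.384444e-01 2.335198e-03
83.9580 1.397835e-01 1.738867e-02 7.639739e-04 1.368970e-01 2.122557e-03
88.6658 1.378910e-01 1.775773e-02 6.468627e-04 1.353149e-01 1.929279e-03
93.6375 1.360006e-01 1.814281e-02 5.477038e-04 1.336993e-01 1.753601e-03
98.8880 1.341091e-01 1.854001e-02 4.637451e-04 1.320514e-01 1.593920e-03
104.4330 1.322142e-01 1.894582e-02 3.926567e-04 1.303728e-01 1.448779e-03
110.2888 1.303141e-01 1.935709e-02 3.324655e-04 1.286648e-01 1.316855e-03
116.4730 1.284077e-01 1.977095e-02 2.815012e-04 1.269293e-01 1.196943e-03
123.0040 1.264942e-01 2.018484e-02 2.383492e-04 1.251679e-01 1.087951e-03
129.9012 1.245732e-01 2.059640e-02 2.018122e-04 1.233825e-01 9.888829e-04
137.1852 1.226447e-01 2.100350e-02 1.708760e-04 1.215750e-01 8.988362e-04
144.8775 1.207092e-01 2.140420e-02 1.446820e-04 1.197475e-01 8.169891e-04
153.0012 1.187671e-01 2.179673e-02 1.225034e-04 1.179020e-01 7.425948e-04
161.5805 1.168193e-01 2.217948e-02 1.037246e-04 1.160406e-01 6.749749e-04
170.6407 1.148669e-01 2.255101e-02 8.782445e-05 1.141655e-01 6.135123e-04
180.2091 1.129109e-01 2.290999e-02 7.436166e-05 1.122789e-01 5.576465e-04
190.3139 1.109527e-01 2.325524e-02 6.296260e-05 1.103829e-01 5.068677e-04
200.9854 1.089936e-01 2.358572e-02 5.331093e-05 1.084795e-01 4.607128e-04
212.2552 1.070350e-01 2.390046e-02 4.513879e-05 1.065711e-01 4.187608e-04
224.1570 1.050784e-01 2.419865e-02 3.821937e-05 1.046595e-01 3.806288e-04
236.7261 1.031252e-01 2.447956e-02 3.236064e-05 1.027469e-01 3.459691e-04
250.0000 1.011770e-01 2.474255e-02 2.740001e-05 1.008351e-01 3.144655e-04
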