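# element: O  Z: 8  A: 15.9990
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 5.557891e+00 5.088573e+00 5.084954e+00 1.928636e-01 2.800731e-01
10.5607 4.752507e+00 4.309276e+00 4.305471e+00 1.924666e-01 2.545699e-01
11.1529 4.068915e+00 3.649476e+00 3.645476e+00 1.920497e-01 2.313890e-01
11.7783 3.488584e+00 3.090857e+00 3.086653e+00 1.916120e-01 2.103189e-01
12.4387 2.995814e+00 2.617911e+00 2.613494e+00 1.911526e-01 1.911675e-01
13.1362 2.577296e+00 2.217506e+00 2.212866e+00 1.906706e-01 1.737600e-01
13.8728 2.221754e+00 1.878524e+00 1.873651e+00 1.901650e-01 1.579376e-01
14.6507 1.919626e+00 1.591550e+00 1.586435e+00 1.896350e-01 1.435559e-01
15.4722 1.662810e+00 1.348616e+00 1.343247e+00 1.890794e-01 1.304839e-01
16.3397 1.444437e+00 1.142971e+00 1.137338e+00 1.884974e-01 1.186021e-01
17.2560 1.258683e+00 9.689007e-01 9.629930e-01 1.878878e-01 1.078023e-01
18.2235 1.100610e+00 8.215677e-01 8.153738e-01 1.872498e-01 9.798595e-02
19.2454 9.660291e-01 6.968751e-01 6.903834e-01 1.865822e-01 8.906345e-02
20.3245 8.513905e-01 5.913542e-01 5.845531e-01 1.858840e-01 8.095342e-02
21.4642 7.536818e-01 5.020682e-01 4.949457e-01 1.851542e-01 7.358188e-02
22.6678 6.703478e-01 4.265303e-01 4.190745e-01 1.843917e-01 6.688158e-02
23.9388 5.992206e-01 3.626351e-01 3.548337e-01 1.835956e-01 6.079141e-02
25.2811 5.384609e-01 3.085998e-01 3.004405e-01 1.827647e-01 5.525580e-02
26.6987 4.865077e-01 2.629150e-01 2.543853e-01 1.818981e-01 5.022426e-02
28.1958 4.420358e-01 2.243025e-01 2.153900e-01 1.809949e-01 4.565089e-02
29.7768 4.039204e-01 1.916800e-01 1.823725e-01 1.800539e-01 4.149396e-02
31.4465 3.712063e-01 1.641312e-01 1.544162e-01 1.790745e-01 3.771556e-02
33.2098 3.430823e-01 1.408802e-01 1.307454e-01 1.780556e-01 3.428122e-02
35.0719 3.188593e-01 1.212697e-01 1.107032e-01 1.769965e-01 3.115961e-02
37.0385 2.979519e-01 1.047434e-01 9.373325e-02 1.758964e-01 2.832224e-02
39.1154 2.798625e-01 9.082999e-02 7.936468e-02 1.747545e-01 2.574325e-02
41.3087 2.641682e-01 7.913040e-02 6.719870e-02 1.735704e-01 2.339909e-02
43.6250 2.505094e-01 6.930655e-02 5.689767e-02 1.723434e-01 2.126839e-02
46.0712 2.385804e-01 6.107208e-02 4.817571e-02 1.710730e-01 1.933171e-02
48.6545 2.281211e-01 5.418437e-02 4.079075e-02 1.697590e-01 1.757139e-02
51.3827 2.189102e-01 4.843784e-02 3.453785e-02 1.684010e-01 1.597135e-02
54.2639 2.107595e-01 4.365825e-02 2.924347e-02 1.669990e-01 1.451702e-02
57.3066 2.035087e-01 3.969789e-02 2.476068e-02 1.655529e-01 1.319511e-02
60.5200 1.970215e-01 3.643152e-02 2.096506e-02 1.640628e-01 1.199358e-02
63.9135 1.911818e-01 3.375286e-02 1.775128e-02 1.625291e-01 1.090145e-02
67.4973 1.858910e-01 3.157176e-02 1.503015e-02 1.609521e-01 9.908778e-03
71.2821 1.810649e-01 2.981163e-02 1.272615e-02 1.593323e-01 9.006494e-03
75.2791 1.766321e-01 2.840744e-02 1.077533e-02 1.576704e-01 8.186371e-03
79.5002 1.725319e-01 2.730387e-02 9.123558e-03 1.559674e-01 7.440928e-03
83.9580 1.687124e-01 2.645388e-02 7.724988e-03 1.542241e-01 6.763365e-03
88.6658 1.651300e-01 2.581740e-02 6.540809e-03 1.524417e-01 6.147499e-03
93.6375 1.617475e-01 2.536028e-02 5.538154e-03 1.506216e-01 5.587714e-03
98.8880 1.585333e-01 2.505339e-02 4.689199e-03 1.487652e-01 5.078902e-03
104.4330 1.554609e-01 2.487183e-02 3.970382e-03 1.468741e-01 4.616422e-03
110.2888 1.525078e-01 2.479433e-02 3.361754e-03 1.449500e-01 4.196055e-03
116.4730 1.496552e-01 2.480266e-02 2.846423e-03 1.429948e-01 3.813966e-03
123.0040 1.468872e-01 2.488121e-02 2.410089e-03 1.410104e-01 3.466670e-03
129.9012 1.441907e-01 2.501658e-02 2.040641e-03 1.389990e-01 3.150999e-03
137.1852 1.415547e-01 2.519724e-02 1.727827e-03 1.369628e-01 2.864072e-03
144.8775 1.389702e-01 2.541330e-02 1.462965e-03 1.349040e-01 2.603272e-03
153.0012 1.364298e-01 2.565624e-02 1.238704e-03 1.328249e-01 2.366221e-03
161.5805 1.339275e-01 2.591871e-02 1.048820e-03 1.307279e-01 2.150755e-03
170.6407 1.314585e-01 2.619440e-02 8.880445e-04 1.286155e-01 1.954909e-03
180.2091 1.290189e-01 2.647786e-02 7.519143e-04 1.264901e-01 1.776897e-03
190.3139 1.266058e-01 2.676439e-02 6.366518e-04 1.243541e-01 1.615095e-03
200.9854 1.242169e-01 2.704997e-02 5.390581e-04 1.222098e-01 1.468026e-03
212.2552 1.218506e-01 2.733113e-02 4.564248e-04 1.200598e-01 1.334349e-03
224.1570 1.195056e-01 2.760489e-02 3.864584e-04 1.179063e-01 1.212844e-03
236.7261 1.171812e-01 2.786871e-02 3.272174e-04 1.157516e-01 1.102404e-03
250.0000 1.148769e-01 2.812042e-02 2.770576e-04 1.135978e-01 1.002020e-03
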