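# element: Na  Z: 11  A: 22.9900
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 1.395216e+01 1.333898e+01 1.333552e+01 1.845469e-01 4.320977e-01
10.5607 1.186821e+01 1.129493e+01 1.129129e+01 1.841670e-01 3.927513e-01
11.1529 1.010118e+01 9.564252e+00 9.560424e+00 1.837681e-01 3.569878e-01
11.7783 8.602717e+00 8.098910e+00 8.094887e+00 1.833493e-01 3.244808e-01
12.4387 7.331848e+00 6.858231e+00 6.854005e+00 1.829097e-01 2.949339e-01
13.1362 6.253866e+00 5.807780e+00 5.803340e+00 1.824485e-01 2.680775e-01
13.8728 5.339365e+00 4.918396e+00 4.913734e+00 1.819647e-01 2.436666e-01
14.6507 4.563433e+00 4.165392e+00 4.160497e+00 1.814575e-01 2.214786e-01
15.4722 3.904963e+00 3.527863e+00 3.522726e+00 1.809259e-01 2.013110e-01
16.3397 3.346068e+00 2.988109e+00 2.982720e+00 1.803690e-01 1.829798e-01
17.2560 2.871596e+00 2.531145e+00 2.525492e+00 1.797857e-01 1.663178e-01
18.2235 2.468703e+00 2.144281e+00 2.138354e+00 1.791752e-01 1.511731e-01
19.2454 2.126505e+00 1.816773e+00 1.810561e+00 1.785364e-01 1.374074e-01
20.3245 1.835780e+00 1.539524e+00 1.533017e+00 1.778683e-01 1.248952e-01
21.4642 1.588710e+00 1.304833e+00 1.298017e+00 1.771700e-01 1.135224e-01
22.6678 1.378667e+00 1.106176e+00 1.099042e+00 1.764404e-01 1.031851e-01
23.9388 1.200035e+00 9.380322e-01 9.305671e-01 1.756785e-01 9.378920e-02
25.2811 1.048051e+00 7.957261e-01 7.879185e-01 1.748835e-01 8.524884e-02
26.6987 9.186773e-01 6.752987e-01 6.671368e-01 1.740543e-01 7.748617e-02
28.1958 8.084904e-01 5.733981e-01 5.648700e-01 1.731900e-01 7.043035e-02
29.7768 7.145866e-01 4.871861e-01 4.782799e-01 1.722897e-01 6.401703e-02
31.4465 6.345035e-01 4.142595e-01 4.049634e-01 1.713524e-01 5.818770e-02
33.2098 5.661524e-01 3.525834e-01 3.428857e-01 1.703775e-01 5.288919e-02
35.0719 5.077612e-01 3.004349e-01 2.903240e-01 1.693641e-01 4.807315e-02
37.0385 4.578267e-01 2.563550e-01 2.458196e-01 1.683114e-01 4.369565e-02
39.1154 4.150730e-01 2.191083e-01 2.081374e-01 1.672188e-01 3.971677e-02
41.3087 3.784175e-01 1.876488e-01 1.762316e-01 1.660857e-01 3.610020e-02
43.6250 3.469412e-01 1.610905e-01 1.492167e-01 1.649116e-01 3.281295e-02
46.0712 3.198640e-01 1.386832e-01 1.263430e-01 1.636960e-01 2.982503e-02
48.6545 2.965234e-01 1.197916e-01 1.069756e-01 1.624386e-01 2.710920e-02
51.3827 2.763569e-01 1.038777e-01 9.057707e-02 1.611392e-01 2.464066e-02
54.2639 2.588869e-01 9.048550e-02 7.669232e-02 1.597976e-01 2.239690e-02
57.3066 2.437074e-01 7.922908e-02 6.493599e-02 1.584139e-01 2.035746e-02
60.5200 2.304737e-01 6.978132e-02 5.498182e-02 1.569881e-01 1.850373e-02
63.9135 2.188929e-01 6.186510e-02 4.655354e-02 1.555205e-01 1.681880e-02
67.4973 2.087160e-01 5.524555e-02 3.941725e-02 1.540115e-01 1.528730e-02
71.2821 1.997317e-01 4.972362e-02 3.337489e-02 1.524616e-01 1.389525e-02
75.2791 1.917601e-01 4.513056e-02 2.825879e-02 1.508714e-01 1.262996e-02
79.5002 1.846486e-01 4.132328e-02 2.392694e-02 1.492417e-01 1.147989e-02
83.9580 1.782673e-01 3.818039e-02 2.025913e-02 1.475736e-01 1.043454e-02
88.6658 1.725061e-01 3.559891e-02 1.715356e-02 1.458681e-01 9.484383e-03
93.6375 1.672713e-01 3.349142e-02 1.452406e-02 1.441265e-01 8.620744e-03
98.8880 1.624835e-01 3.178368e-02 1.229763e-02 1.423502e-01 7.835748e-03
104.4330 1.580753e-01 3.041264e-02 1.041250e-02 1.405406e-01 7.122232e-03
110.2888 1.539895e-01 2.932471e-02 8.816349e-03 1.386994e-01 6.473688e-03
116.4730 1.501776e-01 2.847431e-02 7.464872e-03 1.368285e-01 5.884201e-03
123.0040 1.465987e-01 2.782269e-02 6.320566e-03 1.349298e-01 5.348391e-03
129.9012 1.432182e-01 2.733684e-02 5.351674e-03 1.330051e-01 4.861372e-03
137.1852 1.400067e-01 2.698867e-02 4.531304e-03 1.310567e-01 4.418700e-03
144.8775 1.369397e-01 2.675424e-02 3.836691e-03 1.290866e-01 4.016337e-03
153.0012 1.339964e-01 2.661316e-02 3.248557e-03 1.270972e-01 3.650614e-03
161.5805 1.311595e-01 2.654803e-02 2.750579e-03 1.250907e-01 3.318192e-03
170.6407 1.284143e-01 2.654403e-02 2.328937e-03 1.230694e-01 3.016041e-03
180.2091 1.257489e-01 2.658852e-02 1.971929e-03 1.210356e-01 2.741403e-03
190.3139 1.231531e-01 2.667070e-02 1.669648e-03 1.189917e-01 2.491774e-03
200.9854 1.206185e-01 2.678141e-02 1.413704e-03 1.169399e-01 2.264875e-03
212.2552 1.181382e-01 2.691280e-02 1.196994e-03 1.148826e-01 2.058638e-03
224.1570 1.157066e-01 2.705822e-02 1.013505e-03 1.128219e-01 1.871180e-03
236.7261 1.133191e-01 2.721199e-02 8.581423e-04 1.107601e-01 1.700792e-03
250.0000 1.109718e-01 2.736929e-02 7.265959e-04 1.086993e-01 1.545920e-03
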