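# element: Si  Z: 14  A: 28.0860
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 3.065030e+01 2.981529e+01 2.981168e+01 1.922610e-01 6.463525e-01
10.5607 2.602115e+01 2.524558e+01 2.524179e+01 1.918653e-01 5.874963e-01
11.1529 2.209787e+01 2.137641e+01 2.137242e+01 1.914497e-01 5.339994e-01
11.7783 1.877259e+01 1.810039e+01 1.809620e+01 1.910133e-01 4.853740e-01
12.4387 1.595393e+01 1.532660e+01 1.532219e+01 1.905554e-01 4.411763e-01
13.1362 1.356450e+01 1.297805e+01 1.297342e+01 1.900749e-01 4.010032e-01
13.8728 1.153876e+01 1.098956e+01 1.098470e+01 1.895709e-01 3.644882e-01
14.6507 9.821172e+00 9.305931e+00 9.300831e+00 1.890425e-01 3.312983e-01
15.4722 8.364707e+00 7.880439e+00 7.875087e+00 1.884887e-01 3.011306e-01
16.3397 7.129517e+00 6.673514e+00 6.667899e+00 1.879084e-01 2.737099e-01
17.2560 6.081849e+00 5.651652e+00 5.645762e+00 1.873008e-01 2.487862e-01
18.2235 5.193108e+00 4.786486e+00 4.780312e+00 1.866647e-01 2.261319e-01
19.2454 4.439067e+00 4.053999e+00 4.047528e+00 1.859992e-01 2.055406e-01
20.3245 3.799201e+00 3.433853e+00 3.427074e+00 1.853032e-01 1.868242e-01
21.4642 3.256118e+00 2.908830e+00 2.901730e+00 1.845757e-01 1.698122e-01
22.6678 2.795083e+00 2.464350e+00 2.456918e+00 1.838156e-01 1.543493e-01
23.9388 2.403608e+00 2.088069e+00 2.080292e+00 1.830219e-01 1.402944e-01
25.2811 2.071112e+00 1.769533e+00 1.761400e+00 1.821937e-01 1.275193e-01
26.6987 1.788628e+00 1.499894e+00 1.491391e+00 1.813298e-01 1.159075e-01
28.1958 1.548555e+00 1.271657e+00 1.262772e+00 1.804294e-01 1.053531e-01
29.7768 1.344451e+00 1.078478e+00 1.069199e+00 1.794914e-01 9.575975e-02
31.4465 1.170855e+00 9.149842e-01 9.052996e-01 1.785150e-01 8.703996e-02
33.2098 1.023138e+00 7.766274e-01 7.665243e-01 1.774993e-01 7.911418e-02
35.0719 8.973758e-01 6.595557e-01 6.490222e-01 1.764435e-01 7.191012e-02
37.0385 7.902411e-01 5.605079e-01 5.495322e-01 1.753468e-01 6.536205e-02
39.1154 6.989121e-01 4.767227e-01 4.652932e-01 1.742086e-01 5.941025e-02
41.3087 6.209960e-01 4.058619e-01 3.939675e-01 1.730281e-01 5.400041e-02
43.6250 5.544634e-01 3.459455e-01 3.335754e-01 1.718049e-01 4.908318e-02
46.0712 4.975931e-01 2.952970e-01 2.824409e-01 1.705385e-01 4.461372e-02
48.6545 4.489247e-01 2.524967e-01 2.391449e-01 1.692286e-01 4.055124e-02
51.3827 4.072194e-01 2.163425e-01 2.024859e-01 1.678749e-01 3.685868e-02
54.2639 3.714260e-01 1.858162e-01 1.714464e-01 1.664772e-01 3.350236e-02
57.3066 3.406523e-01 1.600556e-01 1.451650e-01 1.650356e-01 3.045167e-02
60.5200 3.141414e-01 1.383305e-01 1.229124e-01 1.635503e-01 2.767877e-02
63.9135 2.912506e-01 1.200225e-01 1.040709e-01 1.620213e-01 2.515837e-02
67.4973 2.714343e-01 1.046076e-01 8.811764e-02 1.604492e-01 2.286747e-02
71.2821 2.542296e-01 9.164200e-02 7.460990e-02 1.588345e-01 2.078518e-02
75.2791 2.392431e-01 8.074981e-02 6.317279e-02 1.571778e-01 1.889250e-02
79.5002 2.261412e-01 7.161242e-02 5.348890e-02 1.554801e-01 1.717217e-02
83.9580 2.146402e-01 6.395985e-02 4.528947e-02 1.537422e-01 1.560849e-02
88.6658 2.044996e-01 5.756332e-02 3.834696e-02 1.519655e-01 1.418720e-02
93.6375 1.955150e-01 5.222887e-02 3.246867e-02 1.501510e-01 1.289532e-02
98.8880 1.875130e-01 4.779204e-02 2.749148e-02 1.483004e-01 1.172109e-02
104.4330 1.803462e-01 4.411340e-02 2.327725e-02 1.464152e-01 1.065378e-02
110.2888 1.738898e-01 4.107465e-02 1.970903e-02 1.444971e-01 9.683654e-03
116.4730 1.680377e-01 3.857543e-02 1.668779e-02 1.425480e-01 8.801870e-03
123.0040 1.626999e-01 3.653060e-02 1.412969e-02 1.405699e-01 8.000380e-03
129.9012 1.578003e-01 3.486787e-02 1.196372e-02 1.385648e-01 7.271873e-03
137.1852 1.532744e-01 3.352586e-02 1.012977e-02 1.365349e-01 6.609703e-03
144.8775 1.490673e-01 3.245247e-02 8.576960e-03 1.344825e-01 6.007830e-03
153.0012 1.451328e-01 3.160343e-02 7.262180e-03 1.324099e-01 5.460763e-03
161.5805 1.414320e-01 3.094114e-02 6.148945e-03 1.303195e-01 4.963511e-03
170.6407 1.379316e-01 3.043365e-02 5.206360e-03 1.282137e-01 4.511539e-03
180.2091 1.346039e-01 3.005383e-02 4.408266e-03 1.260949e-01 4.100722e-03
190.3139 1.314254e-01 2.977862e-02 3.732514e-03 1.239655e-01 3.727314e-03
200.9854 1.283763e-01 2.958843e-02 3.160349e-03 1.218280e-01 3.387909e-03
212.2552 1.254400e-01 2.946663e-02 2.675892e-03 1.196847e-01 3.079409e-03
224.1570 1.226026e-01 2.939909e-02 2.265699e-03 1.175379e-01 2.799001e-03
236.7261 1.198525e-01 2.937383e-02 1.918385e-03 1.153899e-01 2.544127e-03
250.0000 1.171797e-01 2.938068e-02 1.624312e-03 1.132429e-01 2.312461e-03
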