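# element: K  Z: 19  A: 39.0980
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 7.760948e+01 7.642931e+01 7.642579e+01 1.874356e-01 9.962508e-01
10.5607 6.580291e+01 6.471402e+01 6.471032e+01 1.870498e-01 9.055332e-01
11.1529 5.580046e+01 5.479463e+01 5.479074e+01 1.866446e-01 8.230762e-01
11.7783 4.732610e+01 4.639584e+01 4.639175e+01 1.862193e-01 7.481277e-01
12.4387 4.014604e+01 3.928456e+01 3.928026e+01 1.857728e-01 6.800039e-01
13.1362 3.406230e+01 3.326342e+01 3.325891e+01 1.853043e-01 6.180834e-01
13.8728 2.890720e+01 2.816532e+01 2.816058e+01 1.848130e-01 5.618013e-01
14.6507 2.453873e+01 2.384876e+01 2.384379e+01 1.842979e-01 5.106442e-01
15.4722 2.083663e+01 2.019394e+01 2.018872e+01 1.837579e-01 4.641455e-01
16.3397 1.769902e+01 1.709942e+01 1.709395e+01 1.831923e-01 4.218808e-01
17.2560 1.503965e+01 1.447932e+01 1.447358e+01 1.825999e-01 3.834648e-01
18.2235 1.278542e+01 1.226092e+01 1.225490e+01 1.819798e-01 3.485468e-01
19.2454 1.087446e+01 1.038263e+01 1.037632e+01 1.813310e-01 3.168085e-01
20.3245 9.254323e+00 8.792320e+00 8.785710e+00 1.806525e-01 2.879602e-01
21.4642 7.880612e+00 7.445852e+00 7.438930e+00 1.799432e-01 2.617388e-01
22.6678 6.715708e+00 6.305847e+00 6.298601e+00 1.792022e-01 2.379052e-01
23.9388 5.727745e+00 5.340657e+00 5.333075e+00 1.784284e-01 2.162417e-01
25.2811 4.889729e+00 4.523487e+00 4.515557e+00 1.776210e-01 1.965510e-01
26.6987 4.178790e+00 3.831647e+00 3.823358e+00 1.767788e-01 1.786532e-01
28.1958 3.575553e+00 3.245929e+00 3.237267e+00 1.759009e-01 1.623852e-01
29.7768 3.063605e+00 2.750065e+00 2.741020e+00 1.749865e-01 1.475986e-01
31.4465 2.629036e+00 2.330285e+00 2.320843e+00 1.740346e-01 1.341584e-01
33.2098 2.260063e+00 1.974926e+00 1.965076e+00 1.730444e-01 1.219421e-01
35.0719 1.946699e+00 1.674115e+00 1.663845e+00 1.720151e-01 1.108382e-01
37.0385 1.680482e+00 1.419491e+00 1.408791e+00 1.709459e-01 1.007453e-01
39.1154 1.454242e+00 1.203977e+00 1.192835e+00 1.698363e-01 9.157157e-02
41.3087 1.261901e+00 1.021578e+00 1.009982e+00 1.686854e-01 8.323315e-02
43.6250 1.098307e+00 8.672197e-01 8.551601e-01 1.674929e-01 7.565402e-02
46.0712 9.590941e-01 7.366042e-01 7.240708e-01 1.662583e-01 6.876504e-02
48.6545 8.405611e-01 6.260931e-01 6.130765e-01 1.649813e-01 6.250336e-02
51.3827 7.395701e-01 5.326055e-01 5.190967e-01 1.636615e-01 5.681186e-02
54.2639 6.534608e-01 4.535323e-01 4.395233e-01 1.622990e-01 5.163863e-02
57.3066 5.799778e-01 3.866646e-01 3.721478e-01 1.608936e-01 4.693647e-02
60.5200 5.172084e-01 3.301317e-01 3.151005e-01 1.594455e-01 4.266248e-02
63.9135 4.635306e-01 2.823493e-01 2.667981e-01 1.579549e-01 3.877767e-02
67.4973 4.175689e-01 2.419761e-01 2.259000e-01 1.564222e-01 3.524662e-02
71.2821 3.781565e-01 2.078760e-01 1.912713e-01 1.548480e-01 3.203709e-02
75.2791 3.443037e-01 1.790868e-01 1.619510e-01 1.532330e-01 2.911983e-02
79.5002 3.151712e-01 1.547938e-01 1.371252e-01 1.515778e-01 2.646820e-02
83.9580 2.900466e-01 1.343067e-01 1.161050e-01 1.498836e-01 2.405803e-02
88.6658 2.683257e-01 1.170411e-01 9.830698e-02 1.481514e-01 2.186733e-02
93.6375 2.494959e-01 1.025015e-01 8.323729e-02 1.463825e-01 1.987611e-02
98.8880 2.331222e-01 9.026873e-02 7.047767e-02 1.445784e-01 1.806621e-02
104.4330 2.188356e-01 7.998720e-02 5.967400e-02 1.427405e-01 1.642112e-02
110.2888 2.063228e-01 7.135583e-02 5.052645e-02 1.408705e-01 1.492583e-02
116.4730 1.953182e-01 6.411945e-02 4.278114e-02 1.389703e-01 1.356670e-02
123.0040 1.855963e-01 5.806183e-02 3.622313e-02 1.370418e-01 1.233133e-02
129.9012 1.769659e-01 5.299971e-02 3.067041e-02 1.350870e-01 1.120845e-02
137.1852 1.692648e-01 4.877777e-02 2.596888e-02 1.331081e-01 1.018782e-02
144.8775 1.623554e-01 4.526434e-02 2.198806e-02 1.311072e-01 9.260126e-03
153.0012 1.561210e-01 4.234779e-02 1.861746e-02 1.290867e-01 8.416908e-03
161.5805 1.504628e-01 3.993351e-02 1.576355e-02 1.270487e-01 7.650473e-03
170.6407 1.452967e-01 3.794126e-02 1.334712e-02 1.249958e-01 6.953828e-03
180.2091 1.405519e-01 3.630302e-02 1.130111e-02 1.229302e-01 6.320619e-03
190.3139 1.361680e-01 3.496114e-02 9.568743e-03 1.208542e-01 5.745070e-03
200.9854 1.320942e-01 3.386672e-02 8.101930e-03 1.187704e-01 5.221929e-03
212.2552 1.282872e-01 3.297831e-02 6.859968e-03 1.166808e-01 4.746425e-03
224.1570 1.247106e-01 3.226078e-02 5.808389e-03 1.145879e-01 4.314220e-03
236.7261 1.213333e-01 3.168437e-02 4.918009e-03 1.124939e-01 3.921372e-03
250.0000 1.181292e-01 3.122385e-02 4.164117e-03 1.104007e-01 3.564295e-03
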