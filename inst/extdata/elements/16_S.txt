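# element: S  Z: 16  A: 32.0600
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 4.653511e+01 4.555560e+01 4.555199e+01 1.924906e-01 7.906343e-01
10.5607 3.947996e+01 3.857303e+01 3.856923e+01 1.920944e-01 7.186399e-01
11.1529 3.350175e+01 3.266086e+01 3.265687e+01 1.916783e-01 6.532013e-01
11.7783 2.843579e+01 2.765502e+01 2.765083e+01 1.912414e-01 5.937214e-01
12.4387 2.414262e+01 2.341658e+01 2.341218e+01 1.907829e-01 5.396577e-01
13.1362 2.050409e+01 1.982790e+01 1.982327e+01 1.903018e-01 4.905170e-01
13.8728 1.742017e+01 1.678939e+01 1.678452e+01 1.897973e-01 4.458510e-01
14.6507 1.480611e+01 1.421669e+01 1.421159e+01 1.892682e-01 4.052522e-01
15.4722 1.259013e+01 1.203842e+01 1.203306e+01 1.887137e-01 3.683504e-01
16.3397 1.071143e+01 1.019411e+01 1.018849e+01 1.881328e-01 3.348087e-01
17.2560 9.118521e+00 8.632571e+00 8.626675e+00 1.875245e-01 3.043214e-01
18.2235 7.767771e+00 7.310456e+00 7.304274e+00 1.868877e-01 2.766102e-01
19.2454 6.622230e+00 6.191065e+00 6.184586e+00 1.862213e-01 2.514223e-01
20.3245 5.650590e+00 5.243326e+00 5.236538e+00 1.855245e-01 2.285280e-01
21.4642 4.826333e+00 4.440927e+00 4.433818e+00 1.847961e-01 2.077185e-01
22.6678 4.126988e+00 3.761590e+00 3.754149e+00 1.840351e-01 1.888038e-01
23.9388 3.533519e+00 3.186454e+00 3.178667e+00 1.832405e-01 1.716116e-01
25.2811 3.029799e+00 2.699546e+00 2.691403e+00 1.824112e-01 1.559848e-01
26.6987 2.602159e+00 2.287345e+00 2.278832e+00 1.815463e-01 1.417809e-01
28.1958 2.239020e+00 1.938400e+00 1.929505e+00 1.806448e-01 1.288705e-01
29.7768 1.930569e+00 1.643017e+00 1.633727e+00 1.797057e-01 1.171357e-01
31.4465 1.668487e+00 1.392986e+00 1.383290e+00 1.787282e-01 1.064694e-01
33.2098 1.445728e+00 1.181357e+00 1.171242e+00 1.777113e-01 9.677442e-02
35.0719 1.256317e+00 1.002246e+00 9.917001e-01 1.766542e-01 8.796224e-02
37.0385 1.095189e+00 8.506691e-01 8.396803e-01 1.755562e-01 7.995248e-02
39.1154 9.580526e-01 7.224071e-01 7.109639e-01 1.744166e-01 7.267208e-02
41.3087 8.412681e-01 6.138874e-01 6.019788e-01 1.732347e-01 6.605463e-02
43.6250 7.417500e-01 5.220851e-01 5.097002e-01 1.720101e-01 6.003976e-02
46.0712 6.568819e-01 4.444386e-01 4.315672e-01 1.707422e-01 5.457260e-02
48.6545 5.844453e-01 3.787790e-01 3.654113e-01 1.694307e-01 4.960327e-02
51.3827 5.225584e-01 3.232698e-01 3.093967e-01 1.680753e-01 4.508645e-02
54.2639 4.696255e-01 2.763555e-01 2.619686e-01 1.666760e-01 4.098092e-02
57.3066 4.242928e-01 2.367192e-01 2.218109e-01 1.652327e-01 3.724924e-02
60.5200 3.854119e-01 2.032456e-01 1.878090e-01 1.637456e-01 3.385736e-02
63.9135 3.520085e-01 1.749900e-01 1.590194e-01 1.622148e-01 3.077434e-02
67.4973 3.232558e-01 1.511526e-01 1.346430e-01 1.606408e-01 2.797206e-02
71.2821 2.984524e-01 1.310557e-01 1.140033e-01 1.590242e-01 2.542495e-02
75.2791 2.770028e-01 1.141255e-01 9.652746e-02 1.573655e-01 2.310978e-02
79.5002 2.584017e-01 9.987572e-02 8.173056e-02 1.556658e-01 2.100542e-02
83.9580 2.422204e-01 8.789459e-02 6.920191e-02 1.539258e-01 1.909269e-02
88.6658 2.280949e-01 7.783312e-02 5.859381e-02 1.521469e-01 1.735413e-02
93.6375 2.157161e-01 6.939563e-02 4.961184e-02 1.503303e-01 1.577388e-02
98.8880 2.048218e-01 6.233154e-02 4.200674e-02 1.484775e-01 1.433752e-02
104.4330 1.951894e-01 5.642846e-02 3.556744e-02 1.465900e-01 1.303196e-02
110.2888 1.866302e-01 5.150635e-02 3.011523e-02 1.446697e-01 1.184528e-02
116.4730 1.789837e-01 4.741258e-02 2.549880e-02 1.427182e-01 1.076666e-02
123.0040 1.721140e-01 4.401770e-02 2.159004e-02 1.407377e-01 9.786262e-03
129.9012 1.659058e-01 4.121196e-02 1.828045e-02 1.387302e-01 8.895135e-03
137.1852 1.602613e-01 3.890223e-02 1.547821e-02 1.366979e-01 8.085152e-03
144.8775 1.550975e-01 3.700954e-02 1.310552e-02 1.346431e-01 7.348926e-03
153.0012 1.503443e-01 3.546686e-02 1.109655e-02 1.325680e-01 6.679740e-03
161.5805 1.459422e-01 3.421733e-02 9.395533e-03 1.304751e-01 6.071489e-03
170.6407 1.418407e-01 3.321269e-02 7.955272e-03 1.283668e-01 5.518625e-03
180.2091 1.379974e-01 3.241198e-02 6.735792e-03 1.262455e-01 5.016105e-03
190.3139 1.343762e-01 3.178046e-02 5.703248e-03 1.241136e-01 4.559343e-03
200.9854 1.309467e-01 3.128863e-02 4.828985e-03 1.219735e-01 4.144174e-03
212.2552 1.276832e-01 3.091147e-02 4.088740e-03 1.198276e-01 3.766809e-03
224.1570 1.245641e-01 3.062776e-02 3.461968e-03 1.176783e-01 3.423807e-03
236.7261 1.215711e-01 3.041950e-02 2.931276e-03 1.155277e-01 3.112039e-03
250.0000 1.186888e-01 3.027145e-02 2.481934e-03 1.133782e-01 2.828659e-03
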