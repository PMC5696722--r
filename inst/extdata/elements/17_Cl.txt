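# element: Cl  Z: 17  A: 35.4500
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 5.404937e+01 5.303583e+01 5.303236e+01 1.849634e-01 8.320421e-01
10.5607 4.584378e+01 4.490657e+01 4.490292e+01 1.845827e-01 7.562771e-01
11.1529 3.889125e+01 3.802349e+01 3.801966e+01 1.841828e-01 6.874113e-01
11.7783 3.300012e+01 3.219557e+01 3.219154e+01 1.837631e-01 6.248163e-01
12.4387 2.800808e+01 2.726107e+01 2.725683e+01 1.833225e-01 5.679211e-01
13.1362 2.377764e+01 2.308303e+01 2.307858e+01 1.828602e-01 5.162068e-01
13.8728 2.019239e+01 1.954549e+01 1.954081e+01 1.823754e-01 4.692015e-01
14.6507 1.715370e+01 1.655027e+01 1.654536e+01 1.818670e-01 4.264764e-01
15.4722 1.457806e+01 1.401424e+01 1.400909e+01 1.813342e-01 3.876419e-01
16.3397 1.239472e+01 1.186701e+01 1.186160e+01 1.807760e-01 3.523436e-01
17.2560 1.054377e+01 1.004898e+01 1.004331e+01 1.801914e-01 3.202595e-01
18.2235 8.974430e+00 8.509694e+00 8.503754e+00 1.795795e-01 2.910970e-01
19.2454 7.643725e+00 7.206421e+00 7.200195e+00 1.789393e-01 2.645900e-01
20.3245 6.515229e+00 6.102985e+00 6.096462e+00 1.782697e-01 2.404967e-01
21.4642 5.558090e+00 5.168753e+00 5.161923e+00 1.775698e-01 2.185973e-01
22.6678 4.746171e+00 4.377791e+00 4.370641e+00 1.768385e-01 1.986920e-01
23.9388 4.057330e+00 3.708138e+00 3.700656e+00 1.760750e-01 1.805993e-01
25.2811 3.472807e+00 3.141200e+00 3.133375e+00 1.752782e-01 1.641541e-01
26.6987 2.976707e+00 2.661233e+00 2.653053e+00 1.744471e-01 1.492064e-01
28.1958 2.555562e+00 2.254908e+00 2.246361e+00 1.735808e-01 1.356198e-01
29.7768 2.197960e+00 1.910938e+00 1.902012e+00 1.726785e-01 1.232704e-01
31.4465 1.894233e+00 1.619765e+00 1.610448e+00 1.717391e-01 1.120455e-01
33.2098 1.636184e+00 1.373299e+00 1.363579e+00 1.707620e-01 1.018428e-01
35.0719 1.416869e+00 1.164687e+00 1.154553e+00 1.697463e-01 9.256907e-02
37.0385 1.230400e+00 9.881285e-01 9.775694e-01 1.686912e-01 8.413982e-02
39.1154 1.071790e+00 8.387114e-01 8.277157e-01 1.675961e-01 7.647813e-02
41.3087 9.368080e-01 7.122764e-01 7.008334e-01 1.664605e-01 6.951410e-02
43.6250 8.218691e-01 6.053018e-01 5.934012e-01 1.652837e-01 6.318422e-02
46.0712 7.239336e-01 5.148056e-01 5.024375e-01 1.640654e-01 5.743072e-02
48.6545 6.404241e-01 4.382628e-01 4.254178e-01 1.628052e-01 5.220114e-02
51.3827 5.691552e-01 3.735352e-01 3.602046e-01 1.615028e-01 4.744775e-02
54.2639 5.082735e-01 3.188124e-01 3.049881e-01 1.601583e-01 4.312720e-02
57.3066 4.562073e-01 2.725612e-01 2.582358e-01 1.587714e-01 3.920008e-02
60.5200 4.116233e-01 2.334832e-01 2.186503e-01 1.573424e-01 3.563056e-02
63.9135 3.733905e-01 2.004791e-01 1.851329e-01 1.558715e-01 3.238608e-02
67.4973 3.405496e-01 1.726175e-01 1.567535e-01 1.543591e-01 2.943703e-02
71.2821 3.122866e-01 1.491101e-01 1.327244e-01 1.528056e-01 2.675652e-02
75.2791 2.879108e-01 1.292887e-01 1.123788e-01 1.512118e-01 2.432010e-02
79.5002 2.668361e-01 1.125876e-01 9.515205e-02 1.495785e-01 2.210554e-02
83.9580 2.485653e-01 9.852770e-02 8.056599e-02 1.479067e-01 2.009263e-02
88.6658 2.326762e-01 8.670283e-02 6.821586e-02 1.461973e-01 1.826301e-02
93.6375 2.188107e-01 7.676907e-02 5.775891e-02 1.444518e-01 1.660000e-02
98.8880 2.066647e-01 6.843494e-02 4.890492e-02 1.426714e-01 1.508842e-02
104.4330 1.959804e-01 6.145345e-02 4.140818e-02 1.408577e-01 1.371448e-02
110.2888 1.865387e-01 5.561528e-02 3.506064e-02 1.390124e-01 1.246566e-02
116.4730 1.781540e-01 5.074297e-02 2.968612e-02 1.371373e-01 1.133054e-02
123.0040 1.706685e-01 4.668612e-02 2.513547e-02 1.352343e-01 1.029880e-02
129.9012 1.639487e-01 4.331718e-02 2.128240e-02 1.333053e-01 9.360998e-03
137.1852 1.578810e-01 4.052802e-02 1.801998e-02 1.313524e-01 8.508595e-03
144.8775 1.523694e-01 3.822693e-02 1.525766e-02 1.293780e-01 7.733810e-03
153.0012 1.473324e-01 3.633611e-02 1.291878e-02 1.273840e-01 7.029577e-03
161.5805 1.427009e-01 3.478959e-02 1.093843e-02 1.253730e-01 6.389470e-03
170.6407 1.384164e-01 3.353140e-02 9.261657e-03 1.233471e-01 5.807651e-03
180.2091 1.344295e-01 3.251406e-02 7.841918e-03 1.213087e-01 5.278812e-03
190.3139 1.306981e-01 3.169729e-02 6.639814e-03 1.192602e-01 4.798129e-03
200.9854 1.271870e-01 3.104694e-02 5.621983e-03 1.172038e-01 4.361216e-03
212.2552 1.238661e-01 3.053402e-02 4.760177e-03 1.151418e-01 3.964088e-03
224.1570 1.207102e-01 3.013397e-02 4.030480e-03 1.130766e-01 3.603122e-03
236.7261 1.176978e-01 2.982596e-02 3.412639e-03 1.110101e-01 3.275025e-03
250.0000 1.148109e-01 2.959233e-02 2.889508e-03 1.089446e-01 2.976804e-03
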