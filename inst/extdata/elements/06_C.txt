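# element: C  Z: 6  A: 12.0110
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 2.417586e+00 2.046792e+00 2.043177e+00 1.926749e-01 1.817348e-01
10.5607 2.087438e+00 1.733775e+00 1.729974e+00 1.922783e-01 1.651862e-01
11.1529 1.806789e+00 1.468779e+00 1.464783e+00 1.918618e-01 1.501445e-01
11.7783 1.568140e+00 1.244443e+00 1.240243e+00 1.914245e-01 1.364725e-01
12.4387 1.365135e+00 1.054536e+00 1.050124e+00 1.909656e-01 1.240455e-01
13.1362 1.192382e+00 8.937832e-01 8.891479e-01 1.904841e-01 1.127500e-01
13.8728 1.045311e+00 7.577163e-01 7.528485e-01 1.899790e-01 1.024831e-01
14.6507 9.200433e-01 6.425531e-01 6.374428e-01 1.894494e-01 9.315109e-02
15.4722 8.132911e-01 5.450912e-01 5.397278e-01 1.888944e-01 8.466884e-02
16.3397 7.222638e-01 4.626189e-01 4.569918e-01 1.883130e-01 7.695898e-02
17.2560 6.445938e-01 3.928404e-01 3.869386e-01 1.877040e-01 6.995117e-02
18.2235 5.782720e-01 3.338118e-01 3.276240e-01 1.870666e-01 6.358148e-02
19.2454 5.215933e-01 2.838871e-01 2.774018e-01 1.863996e-01 5.779181e-02
20.3245 4.731098e-01 2.416727e-01 2.348783e-01 1.857021e-01 5.252935e-02
21.4642 4.315924e-01 2.059888e-01 1.988733e-01 1.849731e-01 4.774608e-02
22.6678 3.959973e-01 1.758361e-01 1.683876e-01 1.842113e-01 4.339836e-02
23.9388 3.654376e-01 1.503689e-01 1.425751e-01 1.834159e-01 3.944655e-02
25.2811 3.391599e-01 1.288709e-01 1.207195e-01 1.825859e-01 3.585459e-02
26.6987 3.165240e-01 1.107355e-01 1.022141e-01 1.817202e-01 3.258970e-02
28.1958 2.969854e-01 9.544922e-02 8.654551e-02 1.808178e-01 2.962212e-02
29.7768 2.800813e-01 8.257722e-02 7.327876e-02 1.798778e-01 2.692475e-02
31.4465 2.654180e-01 7.175124e-02 6.204571e-02 1.788993e-01 2.447301e-02
33.2098 2.526606e-01 6.265942e-02 5.253459e-02 1.778814e-01 2.224452e-02
35.0719 2.415238e-01 5.503763e-02 4.448145e-02 1.768234e-01 2.021896e-02
37.0385 2.317649e-01 4.866216e-02 3.766280e-02 1.757243e-01 1.837784e-02
39.1154 2.231774e-01 4.334348e-02 3.188939e-02 1.745836e-01 1.670437e-02
41.3087 2.155849e-01 3.892102e-02 2.700100e-02 1.734006e-01 1.518329e-02
43.6250 2.088374e-01 3.525870e-02 2.286196e-02 1.721748e-01 1.380071e-02
46.0712 2.028071e-01 3.224115e-02 1.935740e-02 1.709056e-01 1.254403e-02
48.6545 1.973847e-01 2.977058e-02 1.639006e-02 1.695929e-01 1.140179e-02
51.3827 1.924774e-01 2.776398e-02 1.387760e-02 1.682363e-01 1.036355e-02
54.2639 1.880057e-01 2.615094e-02 1.175027e-02 1.668356e-01 9.419855e-03
57.3066 1.839021e-01 2.487165e-02 9.949046e-03 1.653909e-01 8.562092e-03
60.5200 1.801087e-01 2.387526e-02 8.423936e-03 1.639023e-01 7.782436e-03
63.9135 1.765765e-01 2.311854e-02 7.132613e-03 1.623701e-01 7.073775e-03
67.4973 1.732635e-01 2.256466e-02 6.039240e-03 1.607946e-01 6.429644e-03
71.2821 1.701341e-01 2.218224e-02 5.113472e-03 1.591764e-01 5.844167e-03
75.2791 1.671578e-01 2.194448e-02 4.329617e-03 1.575162e-01 5.312002e-03
79.5002 1.643090e-01 2.182845e-02 3.665921e-03 1.558148e-01 4.828297e-03
83.9580 1.615658e-01 2.181454e-02 3.103964e-03 1.540732e-01 4.388637e-03
88.6658 1.589098e-01 2.188589e-02 2.628151e-03 1.522926e-01 3.989012e-03
93.6375 1.563253e-01 2.202801e-02 2.225276e-03 1.504743e-01 3.625776e-03
98.8880 1.537995e-01 2.222843e-02 1.884159e-03 1.486197e-01 3.295616e-03
104.4330 1.513213e-01 2.247633e-02 1.595332e-03 1.467304e-01 2.995521e-03
110.2888 1.488817e-01 2.276239e-02 1.350780e-03 1.448082e-01 2.722752e-03
116.4730 1.464734e-01 2.307848e-02 1.143716e-03 1.428549e-01 2.474820e-03
123.0040 1.440903e-01 2.341753e-02 9.683938e-04 1.408725e-01 2.249466e-03
129.9012 1.417276e-01 2.377341e-02 8.199467e-04 1.388631e-01 2.044631e-03
137.1852 1.393815e-01 2.414071e-02 6.942553e-04 1.368288e-01 1.858449e-03
144.8775 1.370491e-01 2.451474e-02 5.878314e-04 1.347720e-01 1.689221e-03
153.0012 1.347281e-01 2.489137e-02 4.977215e-04 1.326950e-01 1.535402e-03
161.5805 1.324171e-01 2.526699e-02 4.214247e-04 1.306001e-01 1.395590e-03
170.6407 1.301150e-01 2.563842e-02 3.568237e-04 1.284897e-01 1.268509e-03
180.2091 1.278215e-01 2.600290e-02 3.021254e-04 1.263663e-01 1.152999e-03
190.3139 1.255362e-01 2.635799e-02 2.558120e-04 1.242324e-01 1.048008e-03
200.9854 1.232595e-01 2.670157e-02 2.165980e-04 1.220903e-01 9.525778e-04
212.2552 1.209916e-01 2.703181e-02 1.833953e-04 1.199424e-01 8.658370e-04
224.1570 1.187332e-01 2.734708e-02 1.552822e-04 1.177910e-01 7.869947e-04
236.7261 1.164852e-01 2.764603e-02 1.314787e-04 1.156384e-01 7.153317e-04
250.0000 1.142482e-01 2.792744e-02 1.113240e-04 1.134867e-01 6.501943e-04
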