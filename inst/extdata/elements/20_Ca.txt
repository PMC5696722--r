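# element: Ca  Z: 20  A: 40.0780
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 9.361651e+01 9.232279e+01 9.231918e+01 1.924762e-01 1.104862e+00
10.5607 7.936371e+01 7.817117e+01 7.816738e+01 1.920800e-01 1.004255e+00
11.1529 6.728941e+01 6.618893e+01 6.618493e+01 1.916639e-01 9.128082e-01
11.7783 5.706022e+01 5.604350e+01 5.603931e+01 1.912271e-01 8.296888e-01
12.4387 4.839383e+01 4.745333e+01 4.744892e+01 1.907686e-01 7.541381e-01
13.1362 4.105113e+01 4.018001e+01 4.017538e+01 1.902876e-01 6.854670e-01
13.8728 3.482964e+01 3.402167e+01 3.401681e+01 1.897831e-01 6.230491e-01
14.6507 2.955787e+01 2.880741e+01 2.880230e+01 1.892541e-01 5.663148e-01
15.4722 2.509058e+01 2.439249e+01 2.438714e+01 1.886996e-01 5.147467e-01
16.3397 2.130477e+01 2.065440e+01 2.064878e+01 1.881187e-01 4.678744e-01
17.2560 1.809627e+01 1.748938e+01 1.748349e+01 1.875104e-01 4.252702e-01
18.2235 1.537682e+01 1.480959e+01 1.480341e+01 1.868737e-01 3.865455e-01
19.2454 1.307171e+01 1.254064e+01 1.253416e+01 1.862074e-01 3.513471e-01
20.3245 1.111764e+01 1.061956e+01 1.061277e+01 1.855106e-01 3.193537e-01
21.4642 9.460974e+00 8.993026e+00 8.985918e+00 1.847823e-01 2.902737e-01
22.6678 8.056311e+00 7.615889e+00 7.608448e+00 1.840213e-01 2.638416e-01
23.9388 6.865176e+00 6.449919e+00 6.442133e+00 1.832268e-01 2.398165e-01
25.2811 5.854981e+00 5.462748e+00 5.454605e+00 1.823976e-01 2.179790e-01
26.6987 4.998120e+00 4.626969e+00 4.618457e+00 1.815328e-01 1.981301e-01
28.1958 4.271204e+00 3.919378e+00 3.910484e+00 1.806313e-01 1.800885e-01
29.7768 3.654420e+00 3.320326e+00 3.311038e+00 1.796923e-01 1.636898e-01
31.4465 3.130981e+00 2.813177e+00 2.803482e+00 1.787148e-01 1.487844e-01
33.2098 2.686664e+00 2.383844e+00 2.373730e+00 1.776980e-01 1.352362e-01
35.0719 2.309419e+00 2.020401e+00 2.009856e+00 1.766410e-01 1.229218e-01
37.0385 1.989033e+00 1.712749e+00 1.701761e+00 1.755431e-01 1.117286e-01
39.1154 1.716853e+00 1.452337e+00 1.440894e+00 1.744035e-01 1.015547e-01
41.3087 1.485546e+00 1.231924e+00 1.220017e+00 1.732218e-01 9.230725e-02
43.6250 1.288897e+00 1.045382e+00 1.032998e+00 1.719972e-01 8.390184e-02
46.0712 1.121639e+00 8.875178e-01 8.746474e-01 1.707294e-01 7.626182e-02
48.6545 9.793063e-01 7.539375e-01 7.405708e-01 1.694180e-01 6.931749e-02
51.3827 8.581154e-01 6.409192e-01 6.270472e-01 1.680627e-01 6.300551e-02
54.2639 7.548576e-01 5.453116e-01 5.309258e-01 1.666635e-01 5.726829e-02
57.3066 6.668129e-01 4.644463e-01 4.495391e-01 1.652204e-01 5.205349e-02
60.5200 5.916751e-01 3.960637e-01 3.806283e-01 1.637333e-01 4.731355e-02
63.9135 5.274888e-01 3.382504e-01 3.222810e-01 1.622027e-01 4.300523e-02
67.4973 4.725958e-01 2.893862e-01 2.728778e-01 1.606288e-01 3.908921e-02
71.2821 4.255899e-01 2.480990e-01 2.310478e-01 1.590123e-01 3.552979e-02
75.2791 3.852782e-01 2.132267e-01 1.956300e-01 1.573537e-01 3.229448e-02
79.5002 3.506493e-01 1.837853e-01 1.656415e-01 1.556541e-01 2.935377e-02
83.9580 3.208451e-01 1.589412e-01 1.402499e-01 1.539143e-01 2.668085e-02
88.6658 2.951376e-01 1.379886e-01 1.187507e-01 1.521355e-01 2.425131e-02
93.6375 2.729093e-01 1.203295e-01 1.005472e-01 1.503191e-01 2.204301e-02
98.8880 2.536363e-01 1.054574e-01 8.513410e-02 1.484664e-01 2.003580e-02
104.4330 2.368741e-01 9.294318e-02 7.208371e-02 1.465791e-01 1.821136e-02
110.2888 2.222457e-01 8.242337e-02 6.103385e-02 1.446588e-01 1.655305e-02
116.4730 2.094311e-01 7.358998e-02 5.167784e-02 1.427075e-01 1.504574e-02
123.0040 1.981589e-01 6.618202e-02 4.375604e-02 1.407272e-01 1.367569e-02
129.9012 1.881988e-01 5.997837e-02 3.704858e-02 1.387198e-01 1.243040e-02
137.1852 1.793555e-01 5.479160e-02 3.136933e-02 1.366877e-01 1.129850e-02
144.8775 1.714633e-01 5.046289e-02 2.656066e-02 1.346330e-01 1.026967e-02
153.0012 1.643817e-01 4.685761e-02 2.248912e-02 1.325581e-01 9.334522e-03
161.5805 1.579916e-01 4.386165e-02 1.904171e-02 1.304654e-01 8.484529e-03
170.6407 1.521919e-01 4.137829e-02 1.612277e-02 1.283572e-01 7.711936e-03
180.2091 1.468970e-01 3.932554e-02 1.365128e-02 1.262360e-01 7.009695e-03
190.3139 1.420343e-01 3.763390e-02 1.155864e-02 1.241043e-01 6.371399e-03
200.9854 1.375424e-01 3.624446e-02 9.786794e-03 1.219644e-01 5.791225e-03
212.2552 1.333691e-01 3.510728e-02 8.286556e-03 1.198187e-01 5.263882e-03
224.1570 1.294703e-01 3.418005e-02 7.016292e-03 1.176695e-01 4.784558e-03
236.7261 1.258087e-01 3.342692e-02 5.940750e-03 1.155191e-01 4.348881e-03
250.0000 1.223526e-01 3.281751e-02 5.030080e-03 1.133697e-01 3.952876e-03
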