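# element: N  Z: 7  A: 14.0070
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 3.751832e+00 3.333587e+00 3.329970e+00 1.927551e-01 2.291074e-01
10.5607 3.220115e+00 2.823315e+00 2.819512e+00 1.923584e-01 2.082451e-01
11.1529 2.768527e+00 2.391301e+00 2.387303e+00 1.919417e-01 1.892825e-01
11.7783 2.384899e+00 2.025550e+00 2.021348e+00 1.915043e-01 1.720467e-01
12.4387 2.058917e+00 1.715906e+00 1.711491e+00 1.910451e-01 1.563803e-01
13.1362 1.781837e+00 1.453771e+00 1.449133e+00 1.905634e-01 1.421404e-01
13.8728 1.546248e+00 1.231862e+00 1.226993e+00 1.900581e-01 1.291973e-01
14.6507 1.345865e+00 1.044017e+00 1.038904e+00 1.895283e-01 1.174327e-01
15.4722 1.175361e+00 8.850141e-01 8.796485e-01 1.889731e-01 1.067394e-01
16.3397 1.030217e+00 7.504348e-01 7.448054e-01 1.883914e-01 9.701978e-02
17.2560 9.066000e-01 6.365369e-01 6.306326e-01 1.877822e-01 8.818526e-02
18.2235 8.012613e-01 5.401520e-01 5.339616e-01 1.871445e-01 8.015519e-02
19.2454 7.114431e-01 4.585975e-01 4.521095e-01 1.864773e-01 7.285634e-02
20.3245 6.348063e-01 3.896019e-01 3.828047e-01 1.857795e-01 6.622211e-02
21.4642 5.693658e-01 3.312422e-01 3.241237e-01 1.850501e-01 6.019199e-02
22.6678 5.134371e-01 2.818898e-01 2.744381e-01 1.842880e-01 5.471096e-02
23.9388 4.655903e-01 2.401660e-01 2.323689e-01 1.834923e-01 4.972904e-02
25.2811 4.246113e-01 2.049034e-01 1.967486e-01 1.826619e-01 4.520076e-02
26.6987 3.894693e-01 1.751135e-01 1.665886e-01 1.817958e-01 4.108482e-02
28.1958 3.592887e-01 1.499593e-01 1.410519e-01 1.808931e-01 3.734368e-02
29.7768 3.333257e-01 1.287321e-01 1.194297e-01 1.799527e-01 3.394320e-02
31.4465 3.109483e-01 1.108317e-01 1.011221e-01 1.789738e-01 3.085236e-02
33.2098 2.916194e-01 9.574993e-02 8.562089e-02 1.779555e-01 2.804298e-02
35.0719 2.748823e-01 8.305646e-02 7.249588e-02 1.768970e-01 2.548941e-02
37.0385 2.603487e-01 7.238678e-02 6.138283e-02 1.757975e-01 2.316837e-02
39.1154 2.476883e-01 6.343220e-02 5.197333e-02 1.746563e-01 2.105868e-02
41.3087 2.366201e-01 5.593122e-02 4.400623e-02 1.734728e-01 1.914110e-02
43.6250 2.269050e-01 4.966233e-02 3.726042e-02 1.722465e-01 1.739813e-02
46.0712 2.183394e-01 4.443781e-02 3.154869e-02 1.709768e-01 1.581387e-02
48.6545 2.107499e-01 4.009861e-02 2.671253e-02 1.696635e-01 1.437387e-02
51.3827 2.039890e-01 3.650988e-02 2.261771e-02 1.683063e-01 1.306500e-02
54.2639 1.979310e-01 3.355726e-02 1.915059e-02 1.669051e-01 1.187532e-02
57.3066 1.924687e-01 3.114377e-02 1.621496e-02 1.654598e-01 1.079396e-02
60.5200 1.875110e-01 2.918709e-02 1.372933e-02 1.639706e-01 9.811074e-03
63.9135 1.829802e-01 2.761732e-02 1.162473e-02 1.624377e-01 8.917687e-03
67.4973 1.788100e-01 2.637506e-02 9.842754e-03 1.608616e-01 8.105651e-03
71.2821 1.749442e-01 2.540982e-02 8.333938e-03 1.592427e-01 7.367559e-03
75.2791 1.713349e-01 2.467861e-02 7.056411e-03 1.575818e-01 6.696676e-03
79.5002 1.679413e-01 2.414481e-02 5.974719e-03 1.558797e-01 6.086883e-03
83.9580 1.647288e-01 2.377721e-02 5.058842e-03 1.541374e-01 5.532617e-03
88.6658 1.616682e-01 2.354912e-02 4.283361e-03 1.523560e-01 5.028823e-03
93.6375 1.587346e-01 2.343774e-02 3.626756e-03 1.505369e-01 4.570903e-03
98.8880 1.559071e-01 2.342354e-02 3.070803e-03 1.486816e-01 4.154681e-03
104.4330 1.531679e-01 2.348977e-02 2.600073e-03 1.467915e-01 3.776360e-03
110.2888 1.505025e-01 2.362203e-02 2.201502e-03 1.448685e-01 3.432488e-03
116.4730 1.478983e-01 2.380792e-02 1.864029e-03 1.429144e-01 3.119929e-03
123.0040 1.453453e-01 2.403678e-02 1.578288e-03 1.409311e-01 2.835831e-03
129.9012 1.428348e-01 2.429937e-02 1.336349e-03 1.389209e-01 2.577603e-03
137.1852 1.403602e-01 2.458772e-02 1.131497e-03 1.368858e-01 2.342889e-03
144.8775 1.379157e-01 2.489492e-02 9.580478e-04 1.348281e-01 2.129548e-03
153.0012 1.354970e-01 2.521500e-02 8.111866e-04 1.327502e-01 1.935633e-03
161.5805 1.331007e-01 2.554275e-02 6.868381e-04 1.306544e-01 1.759376e-03
170.6407 1.307239e-01 2.587368e-02 5.815513e-04 1.285432e-01 1.599169e-03
180.2091 1.283649e-01 2.620388e-02 4.924041e-04 1.264190e-01 1.453551e-03
190.3139 1.260223e-01 2.652997e-02 4.169224e-04 1.242841e-01 1.321192e-03
200.9854 1.236950e-01 2.684902e-02 3.530115e-04 1.221411e-01 1.200885e-03
212.2552 1.213827e-01 2.715849e-02 2.988976e-04 1.199923e-01 1.091534e-03
224.1570 1.190852e-01 2.745620e-02 2.530790e-04 1.178400e-01 9.921397e-04
236.7261 1.168026e-01 2.774029e-02 2.142840e-04 1.156865e-01 9.017964e-04
250.0000 1.145351e-01 2.800914e-02 1.814359e-04 1.135340e-01 8.196797e-04
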