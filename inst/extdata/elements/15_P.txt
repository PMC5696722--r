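# element: P  Z: 15  A: 30.9740
# columns: energy_keV mu_over_rho_cm2g muen_over_rho_cm2g pe_cm2g incoherent_cm2g coherent_cm2g
10.0000 3.691666e+01 3.603696e+01 3.603345e+01 1.867872e-01 6.964182e-01
10.5607 3.132922e+01 3.051349e+01 3.050981e+01 1.864027e-01 6.330030e-01
11.1529 2.659426e+01 2.583677e+01 2.583290e+01 1.859989e-01 5.753624e-01
11.7783 2.258146e+01 2.187699e+01 2.187292e+01 1.855750e-01 5.229704e-01
12.4387 1.918045e+01 1.852425e+01 1.851997e+01 1.851301e-01 4.753492e-01
13.1362 1.629773e+01 1.568550e+01 1.568101e+01 1.846633e-01 4.320644e-01
13.8728 1.385413e+01 1.328195e+01 1.327723e+01 1.841736e-01 3.927210e-01
14.6507 1.178256e+01 1.124689e+01 1.124194e+01 1.836603e-01 3.569602e-01
15.4722 1.002622e+01 9.523837e+00 9.518637e+00 1.831222e-01 3.244558e-01
16.3397 8.536975e+00 8.064960e+00 8.059505e+00 1.825585e-01 2.949111e-01
17.2560 7.274072e+00 6.829768e+00 6.824047e+00 1.819682e-01 2.680568e-01
18.2235 6.202972e+00 5.783973e+00 5.777974e+00 1.813502e-01 2.436478e-01
19.2454 5.294422e+00 4.898543e+00 4.892256e+00 1.807037e-01 2.214615e-01
20.3245 4.523635e+00 4.148899e+00 4.142312e+00 1.800275e-01 2.012954e-01
21.4642 3.869615e+00 3.514226e+00 3.507328e+00 1.793207e-01 1.829657e-01
22.6678 3.314570e+00 2.976904e+00 2.969683e+00 1.785822e-01 1.663050e-01
23.9388 2.843426e+00 2.522009e+00 2.514454e+00 1.778111e-01 1.511614e-01
25.2811 2.443411e+00 2.136910e+00 2.129008e+00 1.770065e-01 1.373968e-01
26.6987 2.103700e+00 1.810909e+00 1.802648e+00 1.761672e-01 1.248856e-01
28.1958 1.815122e+00 1.534948e+00 1.526316e+00 1.752924e-01 1.135136e-01
29.7768 1.569902e+00 1.301358e+00 1.292344e+00 1.743811e-01 1.031772e-01
31.4465 1.361452e+00 1.103647e+00 1.094238e+00 1.734325e-01 9.378196e-02
33.2098 1.184188e+00 9.363152e-01 9.264997e-01 1.724458e-01 8.524227e-02
35.0719 1.033375e+00 7.947083e-01 7.844746e-01 1.714200e-01 7.748019e-02
37.0385 9.050003e-01 6.748841e-01 6.642209e-01 1.703545e-01 7.042492e-02
39.1154 7.956618e-01 5.735051e-01 5.624011e-01 1.692487e-01 6.401209e-02
41.3087 7.024745e-01 4.877452e-01 4.761894e-01 1.681018e-01 5.818321e-02
43.6250 6.229919e-01 4.152113e-01 4.031933e-01 1.669135e-01 5.288511e-02
46.0712 5.551396e-01 3.538770e-01 3.413870e-01 1.656831e-01 4.806944e-02
48.6545 4.971578e-01 3.020267e-01 2.890551e-01 1.644105e-01 4.369228e-02
51.3827 4.475542e-01 2.582072e-01 2.447452e-01 1.630953e-01 3.971371e-02
54.2639 4.050626e-01 2.211883e-01 2.072277e-01 1.617375e-01 3.609741e-02
57.3066 3.686087e-01 1.899279e-01 1.754613e-01 1.603369e-01 3.281042e-02
60.5200 3.372811e-01 1.635437e-01 1.485645e-01 1.588938e-01 2.982273e-02
63.9135 3.103063e-01 1.412882e-01 1.257907e-01 1.574084e-01 2.710710e-02
67.4973 2.870278e-01 1.225284e-01 1.065080e-01 1.558811e-01 2.463876e-02
71.2821 2.668887e-01 1.067283e-01 9.018116e-02 1.543123e-01 2.239518e-02
75.2791 2.494158e-01 9.343369e-02 7.635710e-02 1.527028e-01 2.035589e-02
79.5002 2.342079e-01 8.225969e-02 6.465216e-02 1.510534e-01 1.850231e-02
83.9580 2.209241e-01 7.288031e-02 5.474150e-02 1.493651e-01 1.681750e-02
88.6658 2.092750e-01 6.501932e-02 4.635006e-02 1.476389e-01 1.528612e-02
93.6375 1.990152e-01 5.844257e-02 3.924496e-02 1.458761e-01 1.389418e-02
98.8880 1.899362e-01 5.295161e-02 3.322902e-02 1.440782e-01 1.262899e-02
104.4330 1.818609e-01 4.837819e-02 2.813527e-02 1.422466e-01 1.147900e-02
110.2888 1.746392e-01 4.457967e-02 2.382236e-02 1.403831e-01 1.043374e-02
116.4730 1.681438e-01 4.143506e-02 2.017058e-02 1.384895e-01 9.483651e-03
123.0040 1.622664e-01 3.884173e-02 1.707859e-02 1.365677e-01 8.620079e-03
129.9012 1.569154e-01 3.671262e-02 1.446057e-02 1.346197e-01 7.835143e-03
137.1852 1.520132e-01 3.497386e-02 1.224388e-02 1.326476e-01 7.121683e-03
144.8775 1.474938e-01 3.356275e-02 1.036699e-02 1.306537e-01 6.473189e-03
153.0012 1.433016e-01 3.242605e-02 8.777814e-03 1.286401e-01 5.883747e-03
161.5805 1.393894e-01 3.151858e-02 7.432244e-03 1.266092e-01 5.347978e-03
170.6407 1.357173e-01 3.080199e-02 6.292940e-03 1.245633e-01 4.860997e-03
180.2091 1.322515e-01 3.024369e-02 5.328282e-03 1.225049e-01 4.418359e-03
190.3139 1.289636e-01 2.981605e-02 4.511498e-03 1.204361e-01 4.016028e-03
200.9854 1.258297e-01 2.949557e-02 3.819921e-03 1.183595e-01 3.650332e-03
212.2552 1.228295e-01 2.926234e-02 3.234358e-03 1.162772e-01 3.317936e-03
224.1570 1.199459e-01 2.909943e-02 2.738556e-03 1.141915e-01 3.015808e-03
236.7261 1.171646e-01 2.899252e-02 2.318757e-03 1.121047e-01 2.741192e-03
250.0000 1.144737e-01 2.892943e-02 1.963310e-03 1.100188e-01 2.491581e-03
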