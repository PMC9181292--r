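source_id,position,value,is_proxy
D-lactose,0,0.979604,FALSE
D-lactose,0.072102,0.941525,FALSE
D-lactose,0.151165,0.759231,FALSE
D-lactose,0.201709,0.643353,FALSE
D-lactose,0.217738,0.537298,FALSE
D-lactose,0.27816,0.410144,FALSE
D-lactose,0.281572,0.439655,FALSE
D-lactose,0.282097,0.310207,FALSE
D-lactose,0.326373,0.240076,FALSE
D-lactose,0.392114,0.045693,FALSE
D-lactose,0.394095,0.103978,FALSE
D-lactose,0.440491,0.116693,FALSE
D-lactose,0.448518,0.031335,FALSE
D-lactose,0.449899,0.014963,FALSE
D-lactose,0.614644,0,FALSE
D-lactose,0.675508,0,FALSE
D-lactose,0.701308,0,FALSE
D-lactose,0.729339,0,FALSE
D-lactose,0.776394,0,FALSE
D-lactose,0.810514,0.047925,FALSE
D-lactose,0.889287,0.01756,FALSE
D-lactose,0.905295,0,FALSE
D-lactose,0.959419,0.019626,FALSE
D-lactose,0.993209,0,FALSE
D-lactose,1,0.012043,FALSE
D-galactose,0,0.813194,FALSE
D-galactose,0.024813,0.913473,FALSE
D-galactose,0.120199,1.048063,FALSE
D-galactose,0.180043,0.932923,FALSE
D-galactose,0.310545,0.420995,FALSE
D-galactose,0.32397,0.409453,FALSE
D-galactose,0.359361,0.188789,FALSE
D-galactose,0.36656,0.234707,FALSE
D-galactose,0.374631,0.113789,FALSE
D-galactose,0.377861,0.147509,FALSE
D-galactose,0.433535,0.143091,FALSE
D-galactose,0.46358,0.126317,FALSE
D-galactose,0.466858,0.103991,FALSE
D-galactose,0.466879,0.075833,FALSE
D-galactose,0.504143,0.037239,FALSE
D-galactose,0.565136,0,FALSE
D-galactose,0.584468,0,FALSE
D-galactose,0.618527,0,FALSE
D-galactose,0.650869,0.078925,FALSE
D-galactose,0.780061,0.065316,FALSE
D-galactose,0.794602,0,FALSE
D-galactose,0.856549,0.038418,FALSE
D-galactose,0.874288,0.049565,FALSE
D-galactose,0.936103,0,FALSE
D-galactose,1,0.024276,FALSE
D-glucose,0,0.025957,FALSE
D-glucose,0.007123,0,FALSE
D-glucose,0.191513,0.247068,FALSE
D-glucose,0.264272,0.553637,FALSE
D-glucose,0.292718,0.591916,FALSE
D-glucose,0.315422,0.638438,FALSE
D-glucose,0.315581,0.782546,FALSE
D-glucose,0.376185,0.965715,FALSE
D-glucose,0.465571,0.986038,FALSE
D-glucose,0.46896,1.044287,FALSE
D-glucose,0.522234,0.977714,FALSE
D-glucose,0.547894,0.807901,FALSE
D-glucose,0.617165,0.482096,FALSE
D-glucose,0.63224,0.385956,FALSE
D-glucose,0.657616,0.375144,FALSE
D-glucose,0.720519,0.26058,FALSE
D-glucose,0.780012,0.096728,FALSE
D-glucose,0.782783,0,FALSE
D-glucose,0.853232,0.039673,FALSE
D-glucose,0.859062,0.066925,FALSE
D-glucose,0.875482,0.019435,FALSE
D-glucose,0.888311,0,FALSE
D-glucose,0.929408,0.024673,FALSE
D-glucose,0.987783,0,FALSE
D-glucose,1,0.01879,FALSE
D-fructose,0,0,FALSE
D-fructose,0.005057,0.036403,FALSE
D-fructose,0.160607,0.161638,FALSE
D-fructose,0.164599,0.115268,FALSE
D-fructose,0.196234,0.176142,FALSE
D-fructose,0.230601,0.271598,FALSE
D-fructose,0.272483,0.393709,FALSE
D-fructose,0.281872,0.429385,FALSE
D-fructose,0.32792,0.637915,FALSE
D-fructose,0.336914,0.649938,FALSE
D-fructose,0.354582,0.737384,FALSE
D-fructose,0.379947,0.777803,FALSE
D-fructose,0.39162,0.774059,FALSE
D-fructose,0.411624,0.889618,FALSE
D-fructose,0.425788,1.000595,FALSE
D-fructose,0.464389,0.96831,FALSE
D-fructose,0.47953,0.978054,FALSE
D-fructose,0.647354,0.410424,FALSE
D-fructose,0.666483,0.545267,FALSE
D-fructose,0.680201,0.24365,FALSE
D-fructose,0.715621,0.299166,FALSE
D-fructose,0.822476,0.0531,FALSE
D-fructose,0.929777,0,FALSE
D-fructose,0.988545,0,FALSE
D-fructose,1,0.002691,FALSE
D-trehalose,0,0,FALSE
D-trehalose,0.002009,0.032998,FALSE
D-trehalose,0.07246,0.03706,FALSE
D-trehalose,0.104101,0.066176,FALSE
D-trehalose,0.143049,0.119967,FALSE
D-trehalose,0.148882,0,FALSE
D-trehalose,0.161199,0,FALSE
D-trehalose,0.219959,0,FALSE
D-trehalose,0.231251,0,FALSE
D-trehalose,0.257385,0.104739,FALSE
D-trehalose,0.2805,0,FALSE
D-trehalose,0.317118,0.049387,FALSE
D-trehalose,0.428441,0,FALSE
D-trehalose,0.463677,0.029711,FALSE
D-trehalose,0.623318,0.43089,FALSE
D-trehalose,0.638904,0.527822,FALSE
D-trehalose,0.653228,0.501741,FALSE
D-trehalose,0.665203,0.5841,FALSE
D-trehalose,0.691836,0.601861,FALSE
D-trehalose,0.707138,0.770252,FALSE
D-trehalose,0.73432,0.91071,FALSE
D-trehalose,0.768818,1.040565,FALSE
D-trehalose,0.776666,0.902744,FALSE
D-trehalose,0.817129,1.069777,FALSE
D-trehalose,1,0.528187,FALSE
Oleic acid,0,0.013441,FALSE
Oleic acid,0.012048,0,FALSE
Oleic acid,0.028404,0,FALSE
Oleic acid,0.031234,0.007793,FALSE
Oleic acid,0.168712,0,FALSE
Oleic acid,0.201629,0.043476,FALSE
Oleic acid,0.23802,0.060664,FALSE
Oleic acid,0.29575,0,FALSE
Oleic acid,0.365038,0.104242,FALSE
Oleic acid,0.365894,0,FALSE
Oleic acid,0.380007,0,FALSE
Oleic acid,0.443003,0,FALSE
Oleic acid,0.489282,0,FALSE
Oleic acid,0.506606,0.015524,FALSE
Oleic acid,0.527868,0.164983,FALSE
Oleic acid,0.566392,0.15631,FALSE
Oleic acid,0.570926,0.183144,FALSE
Oleic acid,0.570993,0.139503,FALSE
Oleic acid,0.666771,0.400574,FALSE
Oleic acid,0.752287,0.744097,FALSE
Oleic acid,0.786332,0.824877,FALSE
Oleic acid,0.855938,0.984415,FALSE
Oleic acid,0.883578,0.960672,FALSE
Oleic acid,0.989239,0.690088,FALSE
Oleic acid,1,0.626657,FALSE
D-maltose,0,0,FALSE
D-maltose,0.029583,0,FALSE
D-maltose,0.059672,0.100574,FALSE
D-maltose,0.127471,0.082161,FALSE
D-maltose,0.130259,0.062884,FALSE
D-maltose,0.280533,0.039732,FALSE
D-maltose,0.47516,0,FALSE
D-maltose,0.489854,0,FALSE
D-maltose,0.558059,0,FALSE
D-maltose,0.592485,0.152823,FALSE
D-maltose,0.658033,0.269012,FALSE
D-maltose,0.661934,0.262334,FALSE
D-maltose,0.671802,0.370425,FALSE
D-maltose,0.681299,0.297017,FALSE
D-maltose,0.694613,0.460254,FALSE
D-maltose,0.746579,0.555051,FALSE
D-maltose,0.76258,0.649808,FALSE
D-maltose,0.817723,0.897339,FALSE
D-maltose,0.828793,0.886916,FALSE
D-maltose,0.82982,0.83977,FALSE
D-maltose,0.844447,0.957552,FALSE
D-maltose,0.894437,0.939498,FALSE
D-maltose,0.91364,0.938566,FALSE
D-maltose,0.951575,1.009938,FALSE
D-maltose,1,0.841732,FALSE
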