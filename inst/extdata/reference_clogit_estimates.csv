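species,predator,window,coef,se,or,ci_low,ci_high,p,n_events,concordance,lr_chisq
gemsbok,lion,short,0.475,0.66,1.61,0.44,5.91,0.475,260,0.526,7.64
gemsbok,lion,delayed,-0.471,0.63,0.62,0.18,2.13,0.452,260,0.526,7.64
gemsbok,spotted_hyena,short,-1.114,0.56,0.33,0.11,0.99,0.048,260,0.526,7.64
gemsbok,spotted_hyena,delayed,-0.415,0.36,0.66,0.32,1.33,0.245,260,0.526,7.64
giraffe,lion,short,-0.208,0.41,0.81,0.36,1.81,0.611,351,0.507,5.17
giraffe,lion,delayed,-0.270,0.36,0.76,0.38,1.54,0.451,351,0.507,5.17
giraffe,spotted_hyena,short,-0.032,0.57,0.97,0.32,2.97,0.955,351,0.507,5.17
giraffe,spotted_hyena,delayed,0.823,0.37,2.28,1.10,4.73,0.027,351,0.507,5.17
kudu,lion,short,0.910,0.65,2.48,0.69,8.94,0.164,199,0.518,4.8
kudu,lion,delayed,0.641,0.53,1.90,0.67,5.36,0.227,199,0.518,4.8
kudu,spotted_hyena,short,-16.477,3989.10,0.00,NA,NA,0.997,199,0.518,4.8
kudu,spotted_hyena,delayed,-0.267,0.60,0.77,0.24,2.47,0.655,199,0.518,4.8
mountain_zebra,lion,short,-0.690,0.39,0.50,0.23,1.08,0.079,1174,0.522,33.22
mountain_zebra,lion,delayed,0.230,0.27,1.26,0.75,2.12,0.388,1174,0.522,33.22
mountain_zebra,spotted_hyena,short,-1.302,0.32,0.27,0.14,0.51,0.000,1174,0.522,33.22
mountain_zebra,spotted_hyena,delayed,0.482,0.20,1.62,1.10,2.38,0.014,1174,0.522,33.22
springbok,lion,short,-0.428,0.49,0.65,0.24,1.72,0.386,650,0.518,3.21
springbok,lion,delayed,-0.421,0.31,0.66,0.36,1.21,0.176,650,0.518,3.21
springbok,spotted_hyena,short,-0.105,0.42,0.90,0.40,2.03,0.800,650,0.518,3.21
springbok,spotted_hyena,delayed,-0.191,0.23,0.83,0.53,1.29,0.397,650,0.518,3.21
black_rhino,lion,short,-0.990,0.84,0.37,0.07,1.93,0.239,53,0.614,9.79
black_rhino,lion,delayed,18.699,9814.28,NA,NA,NA,0.998,53,0.614,9.79
black_rhino,spotted_hyena,short,-1.618,0.77,0.20,0.04,0.90,0.035,53,0.614,9.79
black_rhino,spotted_hyena,delayed,0.130,0.95,1.14,0.18,7.33,0.891,53,0.614,9.79
elephant,lion,short,-2.772,0.62,0.06,0.02,0.21,0.000,228,0.582,52.79
elephant,lion,delayed,0.573,0.38,1.77,0.83,3.77,0.137,228,0.582,52.79
elephant,spotted_hyena,short,-1.367,0.69,0.25,0.07,0.99,0.048,228,0.582,52.79
elephant,spotted_hyena,delayed,0.285,0.49,1.33,0.51,3.46,0.559,228,0.582,52.79
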