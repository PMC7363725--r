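measurement,id,mean_total,sd_total,n_total,mean_female,sd_female,n_female,mean_male,sd_male,n_male,p_value,icc
Length of head,I,22.8,0.99,12,22.3,1.10,5,23.4,0.95,3,0.195,0.64
Width of head,II,15.8,0.89,20,15.6,0.56,8,16.6,1.29,5,0.076,0.96
Depth of head,III,18.8,0.75,18,18.5,0.70,8,19.0,0.48,3,0.380,0.95
Face height,IV,14.1,1.04,20,13.8,0.62,8,15.1,1.09,5,0.023,0.96
Lower face height,V,8.3,0.81,20,8.2,0.51,8,8.7,1.16,5,0.303,0.91
Nose height,VI,6.1,0.53,20,5.8,0.44,8,6.6,0.56,5,0.018,0.83
Width of mouth,VII,5.6,0.52,20,5.7,0.38,8,5.8,0.51,5,0.534,0.90
Upper face height,VIII,8.1,0.65,20,7.8,0.58,8,8.7,0.58,5,0.015,0.91
Upper lip height,IX,2.2,0.31,20,2.1,0.25,8,2.5,0.33,5,0.021,0.92
Mandible height,X,4.7,0.61,20,4.4,0.36,8,5.2,0.64,5,0.011,0.66
Mandibular length,XI,14.7,0.81,20,14.4,0.47,8,15.8,0.56,5,0.001,0.88
Palatal width,palatal_width,4.3,0.31,20,4.4,0.23,8,3.9,0.24,5,0.006,0.96
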