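region,mean_total,sd_total,n_total,mean_female,sd_female,n_female,mean_male,sd_male,n_male,p_value,icc
Palate,20.0,2.88,20,20.0,1.78,8,19.4,4.05,5,0.748,0.77
Tongue,35.2,5.16,20,35.0,3.26,8,34.0,3.67,5,0.633,0.90
Hard tissue,21.5,11.06,20,26.4,10.32,8,15.6,9.76,5,0.087,0.95
Mucosa,96.6,12.10,20,94.8,14.55,8,96.9,12.6,5,0.792,0.95
Total,173.3,19.3,20,176.1,18.6,8,165.9,18.2,5,0.353,0.99
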