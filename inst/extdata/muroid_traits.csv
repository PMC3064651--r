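species,n_males,body_mass,testes_mass,total_sperm,pct_normal,pct_acrosome,pct_live,pct_motile
Arvicola terrestris,5,91.56,0.411,36.5,88.1,95.9,68.3,67.0
Chionomys nivalis,6,43.64,0.851,129.4,87.8,96.0,74.3,88.3
Clethrionomys glareolus,6,25.65,0.401,43.2,90.1,91.9,69.7,78.3
Microtus arvalis,8,36.40,0.285,41.6,90.2,98.1,66.6,86.9
Microtus cabrerae,6,44.27,0.142,7.6,76.5,96.1,51.2,55.8
Microtus duodecimcostatus,6,29.76,0.076,4.5,69.4,47.3,74.9,45.0
Microtus lusitanicus,3,17.73,0.093,27.7,81.3,86.8,75.2,78.3
Apodemus sylvaticus,8,30.43,0.961,110.1,93.4,96.1,74.8,82.5
Mus cookii,4,23.67,0.305,62.2,87.5,71.0,75.8,90.8
Mus famulus,3,27.40,0.053,44.9,74.0,65.3,68.3,41.7
Mus macedonicus,3,18.40,0.282,69.9,79.0,86.3,72.7,70.0
Mus musculus bactrianus,3,18.06,0.175,43.6,84.7,67.7,70.3,40.0
Mus musculus castaneus,3,19.50,0.100,26.5,85.0,72.0,63.3,63.3
Mus musculus domesticus,4,16.36,0.135,18.4,80.3,68.8,60.3,87.5
Mus musculus musculus,5,21.13,0.134,23.2,73.0,70.0,88.8,71.7
Mus pahari,5,30.08,0.118,9.1,75.6,73.0,70.8,50.0
Mus spicilegus,5,14.49,0.409,99.4,84.5,77.0,93.8,90.5
Mus spretus,5,17.01,0.295,48.0,79.5,70.8,97.3,98.3
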