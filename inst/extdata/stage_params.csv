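stage,architecture,render_architecture,euploidy,n_cells,n_nuclei,vol_q25,vol_med,vol_q75,fluor_q25_mf,fluor_med_mf,fluor_q75_mf,c_q25,c_med,c_q75
haploid_complement,H,H,N,3,707,0.20,0.30,0.30,0.087,0.15,0.20,0.77,1.3,1.8
gamete,H,H,N,2,572,4.8,6.3,7.2,0.080,0.11,0.14,0.70,1.0,1.3
zygote,H,H,2N,10,556,9.0,13,20,0.13,0.22,0.34,1.1,1.9,3.0
multinuc_juv_in_test,HDP,HDP,2N,10,264,25,51,98,0.40,0.81,1.8,3.5,7.2,16
multinuc_juvenile,H,H,2N,15,69,52,86,120,21,53,77,180,470,6800
multinuc_adult_V1,V1,V,2N,6,14,1600,2600,4500,22,55,140,190,490,1200
multinuc_adult_V2,V2,V,2N,12,65,420,710,1500,5.0,9.6,20,0.44,85,180
multinuc_adult_MB,MB,V,2N,18,121,170,320,610,2.2,6.2,14,20,55,120
multinuc_adult_H,H,H,2N,8,37,100,150,250,1.6,3.0,9.0,14,26,79
multinuc_adult_other,Other,V,2N,3,11,340,440,610,5.0,7.8,15,44,69,140
uninuc_juv_in_test,V,V,N,4,20,420,710,1500,2.7,5.2,11,24,46,100
uninuc_juvenile,V,V,N,10,10,620,710,780,540,610,930,4300,5400,8200
uninuc_adult_VB,VB,V,N,8,8,2000,3700,5300,700,1200,1400,6100,11000,12000
uninuc_adult_VL,VL,V,N,3,3,5600,6100,21000,640,1000,3200,7000,29000,48000
zerfall_nucleus,V,V,N,6,6,5500,7000,9000,420,1100,1400,3700,10000,12000
zerfall_cell,NA,NA,N,17,17,NA,NA,NA,540,1000,1600,4800,9000,14000
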