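"material","density_g_cm3","energy_keV","mu_over_rho_cm2_g","kedge_keV"
"air",0.001205,20,0.7779,NA
"air",0.001205,25,0.50422,NA
"air",0.001205,30,0.3538,NA
"air",0.001205,35,0.29278,NA
"air",0.001205,40,0.2485,NA
"air",0.001205,45,0.22623,NA
"air",0.001205,50,0.208,NA
"air",0.001205,55,0.19702,NA
"air",0.001205,60,0.1875,NA
"air",0.001205,65,0.18131,NA
"air",0.001205,70,0.17577,NA
"air",0.001205,75,0.17076,NA
"air",0.001205,80,0.1662,NA
"air",0.001205,81,0.1655,NA
"air",0.001205,90,0.1597,NA
"air",0.001205,100,0.1541,NA
"air",0.001205,110,0.14954,NA
"air",0.001205,120,0.14549,NA
"air",0.001205,135,0.14018,NA
"air",0.001205,150,0.1356,NA
"soft_tissue",1,20,0.8205,NA
"soft_tissue",1,25,0.53584,NA
"soft_tissue",1,30,0.3783,NA
"soft_tissue",1,35,0.31481,NA
"soft_tissue",1,40,0.2685,NA
"soft_tissue",1,45,0.24527,NA
"soft_tissue",1,50,0.2262,NA
"soft_tissue",1,55,0.21475,NA
"soft_tissue",1,60,0.2048,NA
"soft_tissue",1,65,0.19827,NA
"soft_tissue",1,70,0.19242,NA
"soft_tissue",1,75,0.18712,NA
"soft_tissue",1,80,0.1823,NA
"soft_tissue",1,81,0.18155,NA
"soft_tissue",1,90,0.17532,NA
"soft_tissue",1,100,0.1693,NA
"soft_tissue",1,110,0.16434,NA
"soft_tissue",1,120,0.15995,NA
"soft_tissue",1,135,0.15418,NA
"soft_tissue",1,150,0.1492,NA
"bone",1.92,20,4.001,NA
"bone",1.92,25,2.1833,NA
"bone",1.92,30,1.331,NA
"bone",1.92,35,0.91807,NA
"bone",1.92,40,0.6655,NA
"bone",1.92,45,0.52471,NA
"bone",1.92,50,0.4242,NA
"bone",1.92,55,0.36296,NA
"bone",1.92,60,0.3148,NA
"bone",1.92,65,0.28597,NA
"bone",1.92,70,0.26164,NA
"bone",1.92,75,0.24085,NA
"bone",1.92,80,0.2229,NA
"bone",1.92,81,0.22063,NA
"bone",1.92,90,0.20231,NA
"bone",1.92,100,0.1855,NA
"bone",1.92,110,0.17591,NA
"bone",1.92,120,0.16759,NA
"bone",1.92,135,0.15695,NA
"bone",1.92,150,0.148,NA
"iron",7.874,20,25.68,NA
"iron",7.874,25,13.679,NA
"iron",7.874,30,8.176,NA
"iron",7.874,35,5.2908,NA
"iron",7.874,40,3.629,NA
"iron",7.874,45,2.6202,NA
"iron",7.874,50,1.958,NA
"iron",7.874,55,1.5192,NA
"iron",7.874,60,1.205,NA
"iron",7.874,65,0.99028,NA
"iron",7.874,70,0.82575,NA
"iron",7.874,75,0.69724,NA
"iron",7.874,80,0.5952,NA
"iron",7.874,81,0.5798,NA
"iron",7.874,90,0.46423,NA
"iron",7.874,100,0.3717,NA
"iron",7.874,110,0.31994,NA
"iron",7.874,120,0.27901,NA
"iron",7.874,135,0.23181,NA
"iron",7.874,150,0.1964,NA
"titanium",4.506,20,15.85,NA
"titanium",4.506,25,8.374,NA
"titanium",4.506,30,4.972,NA
"titanium",4.506,35,3.223,NA
"titanium",4.506,40,2.214,NA
"titanium",4.506,45,1.6116,NA
"titanium",4.506,50,1.213,NA
"titanium",4.506,55,0.95396,NA
"titanium",4.506,60,0.7661,NA
"titanium",4.506,65,0.64168,NA
"titanium",4.506,70,0.54458,NA
"titanium",4.506,75,0.46744,NA
"titanium",4.506,80,0.4052,NA
"titanium",4.506,81,0.39632,NA
"titanium",4.506,90,0.32839,NA
"titanium",4.506,100,0.2721,NA
"titanium",4.506,110,0.24188,NA
"titanium",4.506,120,0.21723,NA
"titanium",4.506,135,0.18782,NA
"titanium",4.506,150,0.1649,NA
"copper",8.96,20,33.79,NA
"copper",8.96,25,18.147,NA
"copper",8.96,30,10.92,NA
"copper",8.96,35,7.0782,NA
"copper",8.96,40,4.862,NA
"copper",8.96,45,3.5032,NA
"copper",8.96,50,2.613,NA
"copper",8.96,55,2.0174,NA
"copper",8.96,60,1.593,NA
"copper",8.96,65,1.298,NA
"copper",8.96,70,1.0738,NA
"copper",8.96,75,0.9,NA
"copper",8.96,80,0.763,NA
"copper",8.96,81,0.74166,NA
"copper",8.96,90,0.58308,NA
"copper",8.96,100,0.4584,NA
"copper",8.96,110,0.38644,NA
"copper",8.96,120,0.33066,NA
"copper",8.96,135,0.26776,NA
"copper",8.96,150,0.2217,NA
"gold",19.32,20,78.83,80.7
"gold",19.32,25,42.001,80.7
"gold",19.32,30,25.11,80.7
"gold",19.32,35,16.486,80.7
"gold",19.32,40,11.45,80.7
"gold",19.32,45,8.4159,80.7
"gold",19.32,50,6.39,80.7
"gold",19.32,55,5.0593,80.7
"gold",19.32,60,4.088,80.7
"gold",19.32,65,3.413,80.7
"gold",19.32,70,2.8878,80.7
"gold",19.32,75,2.4717,80.7
"gold",19.32,80,2.137,80.7
"gold",19.32,81,8.8285,80.7
"gold",19.32,90,6.7481,80.7
"gold",19.32,100,5.158,80.7
"gold",19.32,110,4.0584,80.7
"gold",19.32,120,3.2606,80.7
"gold",19.32,135,2.4245,80.7
"gold",19.32,150,1.86,80.7
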