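facility,locality,phys_available,phys_ideal_tu,phys_ideal_tr,hp_available,hp_ideal_tu,hp_ideal_tr
Tapalpa,urban,6.0,5.5,8.7,0.0,4.0,6.2
Jesus Rosal,urban,11.0,60.6,108.9,0.0,37.3,65.7
Satellite,urban,2.0,3.2,4.7,0.0,1.3,2.4
Coapa,urban,10.0,11.1,16.1,0.0,6.6,8.3
GR. Millan,urban,10.0,15.3,29.5,0.0,6.8,13.3
Zacatecas,urban,10.0,24.8,30.3,0.0,14.0,27.1
W. Escalante,urban,10.0,24.3,36.0,0.0,17.5,27.3
Industrial,urban,13.0,43.2,48.4,0.0,25.3,35.0
Rena II,urban,3.0,4.8,6.1,0.0,3.1,6.5
Pedro Escobedo,urban,23.0,81.0,119.9,1.0,55.2,79.8
Toluca,urban,16.0,22.4,33.4,9.0,17.8,36.7
San Rafael,urban,4.0,13.0,26.3,13.0,13.9,30.9
Juanacatlan,rural,2.0,9.7,11.4,NA,NA,NA
Mineral Chico,rural,3.0,6.8,10.5,NA,NA,NA
Cuentepec,rural,4.0,2.0,2.9,NA,NA,NA
Sta Elena,rural,1.0,2.1,2.2,NA,NA,NA
Koben,rural,1.0,1.4,2.6,NA,NA,NA
G. Victoria,rural,12.0,23.6,31.8,NA,NA,NA
R02 Kilometro 30,rural,1.0,4.3,5.2,NA,NA,NA
P. Coyote,rural,1.0,2.5,3.9,NA,NA,NA
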