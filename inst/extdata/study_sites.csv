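id,village,district,n,lat,lon
S01_Duku,Duku,Arua,25,3.267,31.135
S02_Aina,Aina,Arua,19,3.304,31.119
S03_Gangu,Gangu,Arua,20,3.252,31.123
S04_Omugo,Omugo,Arua,15,3.268,31.143
S05_Osugo,Osugo,Moyo,20,3.211,31.725
S06_Belameling,Belameling,Moyo,10,3.479,31.594
S07_Lea,Lea,Moyo,8,3.592,31.606
S08_Orubakulemi,Orubakulemi,Moyo,20,3.692,31.780
S09_Moyo,Moyo,Adjumani,15,3.683,31.727
S10_Olobo,Olobo,Adjumani,24,3.402,32.011
S11_Oringya,Oringya,Adjumani,9,3.486,32.010
S12_Pagirinya,Pagirinya,Adjumani,20,3.378,31.994
S13_Okidi,Okidi,Amuru,26,3.260,32.224
S14_Gorodona,Gorodona,Amuru,25,3.266,32.208
S15_Ngomoromo,Ngomoromo,Lamwo,25,3.669,32.591
S16_Pawor,Pawor,Lamwo,13,3.612,32.682
S17_Lagwel,Lagwel,Lamwo,17,3.441,32.853
S18_Bola,Bola,Kitgum,25,3.293,32.782
S19_Tumangu,Tumangu,Kitgum,20,3.242,32.761
S20_Kitgum,Kitgum,Kitgum,20,3.282,32.805
S21_Kitgum2,Kitgum,Kitgum,17,3.171,32.805
S22_Omido,Omido,Pader,15,3.011,32.732
S23_Pader,Pader,Pader,13,3.050,33.217
S24_Kilak,Kilak,Pader,21,2.740,32.950
S25_Chua,Chua,Pader,25,2.607,32.938
S26_Ocala,Ocala,Oyam,20,2.427,32.629
S27_Akayodebe,Akayo-debe,Oyam,26,2.372,32.676
S28_Koome,Koome,Oyam,15,2.360,32.715
S29_Olepo,Olepo,Kole,24,2.356,32.716
S30_Acanikoma,Acanikoma,Kole,25,2.270,32.521
S31_AputuLwaa,Aputu-Lwaa,Apac,29,2.079,32.676
S32_Apac,Apac,Apac,15,1.976,32.539
S33_Kaberamaido,Kaberamaido,Dokolo,64,1.908,33.160
S34_Aminakwach,Aminakwach,Dokolo,30,1.924,33.156
S35_Aminakwach2,Aminakwach,Dokolo,25,1.925,33.156
S36_Oculoi,Oculoi,Kaberamaido,20,1.847,33.154
S37_Oculoi2,Oculoi,Kaberamaido,25,1.847,33.153
S38_Kangai,Kangai,Kaberamaido,20,1.803,33.103
Bugondo,Bugondo,Serere,18,1.635,33.290
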