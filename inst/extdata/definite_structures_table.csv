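"id","name","active_sites","n_hbonds","affinity_kcal_mol","kd_M","kd_qualifier","ic50_mM","inhibition_pct","inhibition_conc_mM"
"C1","5-Hydroxy-3,7,3',4'-tetramethoxyflavone","ASP-352",1,-8.3,5.54e-11,"",NA,24.34,5
"C2","5-Demethylnobiletin","SER-240",1,-7.5,1e-12,"<",NA,26.11,2.5
"C3","Vicenin-3","THR-310;ARG-315",2,-8.4,7.09e-12,"",0.41,NA,NA
"C4","Naringin","LYS-156;GLU-277;GLN-279;ASP-352",4,-10.2,8.95e-06,"",NA,19.15,10
"C5","8-Hydroxy-3,5,6,7,3',4'-hexamethoxyflavone","LYS-156;ARG-442",2,-8,1e-05,"",NA,22.78,5
"C6","4',5,6,7-Tetramethoxyflavone","ARG-315;GLU-411;ARG-442",3,-8.2,1.18e-07,"",NA,26.77,5
"C7","Tangeretin","HIS-280;ARG-315;ARG-442",4,-8.4,3.99e-05,"",NA,20.54,2.5
"C8","Neohesperidin","LYS-156;ASP-242;GLN-279;ASP-352",5,-10.1,8.95e-06,"",24.15,NA,NA
"C9","Nobiletin","HIS-280;ARG-315;ARG-442",3,-8.2,8.11e-06,"",NA,18.98,10
"C10","Quercetagetin-3,5,6,7,3',4'-hexamethyl ether","LYS-156",1,-7.9,4.54e-07,"",NA,23.21,5
"C11","Sinensetin","GLN-279;ARG-315",2,-7.8,2.4e-06,"",NA,22,10
"C12","Isosinensetin","LYS-13",1,-8.4,2.41e-06,"",NA,9.74,10
"C13","Hesperidin","SER-157;GLU-277;HIS-280;THR-310;ARG-315",5,-10.4,1e-07,"",NA,10.97,10
"C14","Naringenin","TYR-158",1,-8.2,5.72e-06,"",0.4,NA,NA
"C15","Naringenin-7-O-glucoside","LYS-156;GLU-277;GLN-353;GLU-411",4,-10.2,2.94e-06,"",8.9,NA,NA
"C16","Eriocitrin","ASP-69;TYR-158;ASP-215;GLU-277;GLN-353",6,-10.8,3.62e-06,"",6.71,NA,NA
"C17","Vicenin-2","LYS-13;LYS-16;ASN-259",3,-8.8,3.32e-05,"",0.43,NA,NA
"C18","Rhoifolin","ASP-215;ASP-307;ARG-315",4,-10.9,1.58e-05,"",5.28,NA,NA
"C19","Hesperetin","ASP-242;ASN-415",3,-8.7,3.54e-06,"",0.32,NA,NA
"C20","Isoquercitroside","SER-157;PRO-312;GLN-353;GLU-411;ASN-415",5,-9.3,3.45e-06,"",1.46,NA,NA
"C21","5,4'-Dihydroxy-3,6,7,8,3'-pentamethoxyflavone","ARG-442",1,-7.8,NA,"",NA,NA,NA
"C30","2'-Hydroxy-3,4,4',5',6'-pentamethoxychalcone","TYR-158;ARG-442",2,-8,NA,"",NA,NA,NA
"C39","Quercetagetin-3,7,3',4'-tetramethyl ether","GLU-277;ASP-352",3,-8.4,NA,"",NA,NA,NA
"C57","3,3',4',5,6,7,8-Heptamethoxyflavone","SER-240;ARG-315",2,-7.6,NA,"",NA,NA,NA
"C60","Kaempferol-3-O-rutinoside","ASP-307;PRO-312;ARG-315;ARG-442",4,-10.6,4.55e-06,"",2.91,NA,NA
"C78","Dihydroxy-trimethoxyflavone","TYR-158;ARG-442",2,-8,NA,"",NA,NA,NA
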