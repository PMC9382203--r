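species,ecotype,climatic_region,acclimation_temp_C,heating_rate_C_per_h,o2_level_pct_airsat,ctmax_diff_C,significant,reference
Carassius auratus,benthopelagic; FW/BW,subtropical-temperate,17,109,200,0.9,na,ref13
Carassius auratus,benthopelagic; FW/BW,subtropical-temperate,17,109,450,1,na,ref13
Carassius auratus,benthopelagic; FW/BW,subtropical-temperate,27,73,200,0.21,na,ref13
Carassius auratus,benthopelagic; FW/BW,subtropical-temperate,27,73,450,0.81,na,ref13
Fundulus notatus,benthopelagic; FW,subtropical-temperate,30,20,160,-0.01,no,ref34
Notropis lutrensis,benthopelagic; FW,subtropical-temperate,30,20,160,-0.53,no,ref34
Pimephales vigilax,benthopelagic; FW,subtropical-temperate,30,20,160,-0.16,no,ref34
Fundulus heteroclitus,benthopelagic; FW/M/BW,subtropical-temperate,15,18,ns,0.3,no,ref35
Perca fluviatilis,benthopelagic (Biotest population); FW/BW,temperate,23,2,200,0.6,no,ref17
Perca fluviatilis,benthopelagic; FW/BW,temperate,17,2,200,1.1,yes,ref18
Chaenocephalus aceratus,benthopelagic; M,Antarctic,0.5,4,240,0.12,no,ref36
Notothenia coriiceps,benthopelagic; M,Antarctic,0.5,4,240,0.74,no,ref36
Bellapiscis medius,benthic (intertidal); M,temperate,21,2,200,0.13,no,ref9
Forsterygion lapillum,benthopelagic (intertidal/subtidal); M,temperate,21,2,200,0.43,yes,ref9
Atherinomorous sp.,pelagic; M,tropical,20,2,140,1.4,yes,ref8
Dascyllus sp.,reef associated; M,tropical,20,2,140,1.8,yes,ref8
Apistogramma borellii,benthopelagic; FW,tropical-subtropical,31,12,200,0.66,no,ref37
Brycon amazonicus,benthopelagic; FW,tropical,31,12,200,1.4,yes,ref37
Carnegiella strigata,pelagic; FW,tropical,31,12,200,0.51,yes,ref37
Colossoma macropomum,benthopelagic; FW,tropical,31,12,200,0.08,no,ref37
Corydoras pulcher,benthopelagic; FW,tropical,31,12,200,0.81,no,ref37
Corydoras schwartzi,benthopelagic; FW,tropical,31,12,200,0.48,yes,ref37
Paracheirodon axelrodi,pelagic; FW,tropical,31,12,200,0.41,yes,ref37
Oncorhynchus mykiss,benthopelagic; FW/M/BW,temperate,10,2,200,0.87,yes,this_study
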