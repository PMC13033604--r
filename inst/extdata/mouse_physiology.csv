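"table","compartment","volume_ml","vascular_ml","interstitial_ml","plasma_flow_ml_day","lymph_flow_ml_day","species","extravasation_per_day","lymph_exit_per_day"
"compartments","LUNGS",0.2,0.1,0.06,11000,22,NA,NA,NA
"compartments","LIVER",1.4,0.434,0.28,1770,3.54,NA,NA,NA
"compartments","GI",2.5,0.1,0.75,1550,3.1,NA,NA,NA
"compartments","SPLEEN",0.1,0.03,0.02,120,0.24,NA,NA,NA
"compartments","HEART",0.15,0.0105,0.0375,730,1.46,NA,NA,NA
"compartments","KIDNEYS",0.34,0.0816,0.068,1000,2,NA,NA,NA
"compartments","SKIN",2.9,0.058,1.015,1000,2,NA,NA,NA
"compartments","MUSCLE",9.5,0.38,1.235,3000,6,NA,NA,NA
"compartments","BONE",2.8,0.084,0.28,1600,3.2,NA,NA,NA
"compartments","LYMPH_NODES",0.05,0.005,0.03,130,43.74,NA,NA,NA
"compartments","TUMOR1",0.025,0.00175,0.0125,50,0.1,NA,NA,NA
"compartments","TUMOR2",0.025,0.00175,0.0125,50,0.1,NA,NA,NA
"compartments","ARTERIAL_BLOOD",0.5,0.5,0,11000,0,NA,NA,NA
"compartments","VENOUS_BLOOD",1.2,1.2,0,11000,0,NA,NA,NA
"transport","LUNGS",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","LUNGS",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","LUNGS",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","LUNGS",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","LUNGS",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","LUNGS",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","LIVER",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","LIVER",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","LIVER",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","LIVER",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","LIVER",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","LIVER",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","GI",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","GI",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","GI",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","GI",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","GI",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","GI",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","SPLEEN",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","SPLEEN",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","SPLEEN",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","SPLEEN",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","SPLEEN",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","SPLEEN",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","HEART",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","HEART",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","HEART",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","HEART",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","HEART",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","HEART",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","KIDNEYS",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","KIDNEYS",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","KIDNEYS",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","KIDNEYS",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","KIDNEYS",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","KIDNEYS",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","SKIN",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","SKIN",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","SKIN",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","SKIN",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","SKIN",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","SKIN",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","MUSCLE",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","MUSCLE",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","MUSCLE",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","MUSCLE",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","MUSCLE",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","MUSCLE",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","BONE",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","BONE",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","BONE",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","BONE",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","BONE",NA,NA,NA,NA,NA,"TE1",0.8,0.5
"transport","BONE",NA,NA,NA,NA,NA,"APC",0.3,1.5
"transport","LYMPH_NODES",NA,NA,NA,NA,NA,"DC",1,0.3
"transport","LYMPH_NODES",NA,NA,NA,NA,NA,"M1",1,0.2
"transport","LYMPH_NODES",NA,NA,NA,NA,NA,"M2",1,0.2
"transport","LYMPH_NODES",NA,NA,NA,NA,NA,"TREG",0.8,0.3
"transport","LYMPH_NODES",NA,NA,NA,NA,NA,"TE1",0.8,1
"transport","LYMPH_NODES",NA,NA,NA,NA,NA,"APC",0.3,0.05
"transport","TUMOR1",NA,NA,NA,NA,NA,"DC",0.15,0.3
"transport","TUMOR1",NA,NA,NA,NA,NA,"M1",0.15,0.2
"transport","TUMOR1",NA,NA,NA,NA,NA,"M2",0.15,0.2
"transport","TUMOR1",NA,NA,NA,NA,NA,"TREG",0.15,0.3
"transport","TUMOR1",NA,NA,NA,NA,NA,"TE1",0.15,0.5
"transport","TUMOR1",NA,NA,NA,NA,NA,"APC",0.05,2
"transport","TUMOR2",NA,NA,NA,NA,NA,"DC",0.15,0.3
"transport","TUMOR2",NA,NA,NA,NA,NA,"M1",0.15,0.2
"transport","TUMOR2",NA,NA,NA,NA,NA,"M2",0.15,0.2
"transport","TUMOR2",NA,NA,NA,NA,NA,"TREG",0.15,0.3
"transport","TUMOR2",NA,NA,NA,NA,NA,"TE1",0.15,0.5
"transport","TUMOR2",NA,NA,NA,NA,NA,"APC",0.05,2
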