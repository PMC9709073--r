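"level","term","a","b","c","d","ror","ror_low","ror_high","prr","chi2","ic","ic025","ebgm","ebgm05","ror_sig","prr_sig","ic_sig","ebgm_sig","all_four","expected"
"SOC","Gastrointestinal disorders",25,0,107,68,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","General disorders and administration site conditions",14,11,109,66,0.77,0.33,1.8,0.9,0.37,-0.14,-0.61,0.91,0.45,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Blood and lymphatic system disorders",10,15,23,152,4.41,1.77,10.97,3.04,11.45,1.28,0.75,2.42,1.13,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE
"SOC","Nervous system disorders",10,15,65,110,1.13,0.48,2.66,1.08,0.08,0.09,-0.55,1.07,0.52,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Respiratory, thoracic and mediastinal disorders",6,19,29,146,1.59,0.58,4.32,1.45,0.84,0.46,-0.45,1.37,0.59,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Skin and subcutaneous tissue disorders",6,19,34,141,1.31,0.49,3.53,1.24,0.29,0.26,-0.66,1.2,0.52,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Psychiatric disorders",3,22,31,144,0.63,0.18,2.25,0.68,0.51,-0.5,-1.97,0.71,0.24,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Vascular disorders",2,23,24,151,0.55,0.12,2.47,0.58,0.63,-0.7,-2.55,0.62,0.17,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Investigations",1,24,25,150,0.25,0.03,1.93,0.28,2.05,-1.7,-4.42,0.31,0.06,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Musculoskeletal and connective tissue disorders",1,24,24,151,0.26,0.03,2.03,0.29,1.89,-1.64,-4.36,0.32,0.06,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Renal and urinary disorders",1,24,2,173,3.6,0.31,41.27,3.5,1.21,1.42,-0.83,2.67,0.34,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"SOC","Cardiac disorders",0,25,7,168,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
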