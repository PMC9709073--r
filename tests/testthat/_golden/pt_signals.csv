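"level","term","a","b","c","d","ror","ror_low","ror_high","prr","chi2","ic","ic025","ebgm","ebgm05","ror_sig","prr_sig","ic_sig","ebgm_sig","all_four","expected"
"PT","Nausea",25,0,47,128,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Thrombocytopenia",9,16,7,168,13.5,4.44,41.08,9,30.43,2.17,1.84,4.5,1.77,TRUE,TRUE,TRUE,FALSE,FALSE,TRUE
"PT","Fatigue",8,17,59,116,0.93,0.38,2.27,0.95,0.03,-0.07,-0.84,0.96,0.45,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Drug ineffective",7,18,62,113,0.71,0.28,1.79,0.79,0.53,-0.3,-1.17,0.81,0.37,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Headache",7,18,42,133,1.23,0.48,3.15,1.17,0.19,0.19,-0.64,1.14,0.52,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Vomiting",5,20,26,149,1.43,0.49,4.16,1.35,0.44,0.37,-0.66,1.29,0.53,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Constipation",4,21,14,161,2.19,0.66,7.28,2,1.71,0.83,-0.3,1.78,0.65,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Cough",4,21,12,163,2.59,0.76,8.76,2.33,2.48,1,-0.1,2,0.72,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Diarrhoea",4,21,37,138,0.71,0.23,2.2,0.76,0.36,-0.36,-1.59,0.78,0.3,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Rash",4,21,26,149,1.09,0.35,3.44,1.08,0.02,0.09,-1.11,1.07,0.41,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Abdominal pain",3,22,19,156,1.12,0.31,4.1,1.11,0.03,0.13,-1.3,1.09,0.37,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Dizziness",3,22,26,149,0.78,0.22,2.8,0.81,0.14,-0.27,-1.73,0.83,0.28,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Dyspnoea",2,23,19,156,0.71,0.16,3.27,0.74,0.19,-0.39,-2.22,0.76,0.21,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Hypertension",2,23,15,160,0.93,0.2,4.32,0.93,0.01,-0.09,-1.89,0.94,0.26,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Insomnia",2,23,16,159,0.86,0.19,4.01,0.88,0.03,-0.17,-1.98,0.89,0.25,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Malaise",2,23,16,159,0.86,0.19,4.01,0.88,0.03,-0.17,-1.98,0.89,0.25,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Neutropenia",2,23,4,171,3.72,0.64,21.44,3.5,2.45,1.42,-0.13,2.67,0.61,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Pruritus",2,23,8,167,1.82,0.36,9.08,1.75,0.54,0.68,-1.03,1.6,0.41,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Anxiety",1,24,9,166,0.77,0.09,6.34,0.78,0.06,-0.32,-2.95,0.8,0.14,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Asthenia",1,24,17,158,0.39,0.05,3.04,0.41,0.87,-1.17,-3.87,0.44,0.08,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Back pain",1,24,10,165,0.69,0.08,5.61,0.7,0.12,-0.46,-3.1,0.73,0.12,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Renal impairment",1,24,2,173,3.6,0.31,41.27,3.5,1.21,1.42,-0.83,2.67,0.34,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Weight decreased",1,24,8,167,0.87,0.1,7.26,0.88,0.02,-0.17,-2.78,0.89,0.15,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Anaemia",0,25,13,162,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Arthralgia",0,25,14,161,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Blood pressure increased",0,25,7,168,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Emotional distress",0,25,8,167,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Heart rate increased",0,25,8,167,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Hot flush",0,25,10,165,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Memory impairment",0,25,5,170,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Neuropathy peripheral",0,25,3,172,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Palpitations",0,25,5,170,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
"PT","Platelet count decreased",0,25,3,172,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
"PT","Tachycardia",0,25,2,173,,,,,,,,,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
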