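"category","level","count","percent"
"sex","Female",20,80
"sex","Male",0,0
"sex","Unknown",5,20
"age","<40",0,0
"age","40-50",2,8
"age",">50",9,36
"age","Unknown or missing",14,56
"indication","Ovarian cancer",15,60
"indication","Product used for unknown indication",4,16
"indication","Malignant peritoneal neoplasm",3,12
"indication","Fallopian tube cancer",2,8
"serious_outcome","Death",2,8
"serious_outcome","Disability",0,0
"serious_outcome","Hospitalization-initial or prolonged",5,20
"serious_outcome","Life-threatening",2,8
"serious_outcome","Other serious medical events",12,48
"country","US",20,80
"country","DE",2,8
"country","JP",2,8
"country","FR",1,4
"reporter","Consumer",19,76
"reporter","Health professional",1,4
"reporter","Lawyer",0,0
"reporter","Physician",4,16
"reporter","Other health-professional",0,0
"reporter","Pharmacist",0,0
"reporter","Unknown",1,4
"reporting_year","2017",3,12
"reporting_year","2018",7,28
"reporting_year","2019",9,36
"reporting_year","2020",3,12
"reporting_year","2021",3,12
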