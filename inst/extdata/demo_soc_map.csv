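"pt","soc"
"Anaemia","Blood and lymphatic system disorders"
"Thrombocytopenia","Blood and lymphatic system disorders"
"Neutropenia","Blood and lymphatic system disorders"
"Nausea","Gastrointestinal disorders"
"Vomiting","Gastrointestinal disorders"
"Constipation","Gastrointestinal disorders"
"Diarrhoea","Gastrointestinal disorders"
"Abdominal pain","Gastrointestinal disorders"
"Fatigue","General disorders and administration site conditions"
"Asthenia","General disorders and administration site conditions"
"Malaise","General disorders and administration site conditions"
"Drug ineffective","General disorders and administration site conditions"
"Headache","Nervous system disorders"
"Dizziness","Nervous system disorders"
"Neuropathy peripheral","Nervous system disorders"
"Memory impairment","Nervous system disorders"
"Platelet count decreased","Investigations"
"Blood pressure increased","Investigations"
"Weight decreased","Investigations"
"Heart rate increased","Investigations"
"Insomnia","Psychiatric disorders"
"Anxiety","Psychiatric disorders"
"Emotional distress","Psychiatric disorders"
"Rash","Skin and subcutaneous tissue disorders"
"Pruritus","Skin and subcutaneous tissue disorders"
"Photosensitivity reaction","Skin and subcutaneous tissue disorders"
"Hypertension","Vascular disorders"
"Hot flush","Vascular disorders"
"Dyspnoea","Respiratory, thoracic and mediastinal disorders"
"Cough","Respiratory, thoracic and mediastinal disorders"
"Arthralgia","Musculoskeletal and connective tissue disorders"
"Back pain","Musculoskeletal and connective tissue disorders"
"Renal impairment","Renal and urinary disorders"
"Palpitations","Cardiac disorders"
"Tachycardia","Cardiac disorders"
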