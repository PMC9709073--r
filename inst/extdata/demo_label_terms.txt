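Thrombocytopenia
Anaemia
Nausea
Vomiting
Constipation
Fatigue
Headache
Hypertension
Insomnia
Platelet count decreased
Neutropenia
Dizziness
Rash
Diarrhoea
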