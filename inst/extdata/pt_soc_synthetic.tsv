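pt	soc
Chills	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Death	General disorders and administration site conditions
Interstitial lung disease	Respiratory, thoracic, and mediastinal disorders
Pneumonitis	Respiratory, thoracic, and mediastinal disorders
Respiratory failure	Respiratory, thoracic, and mediastinal disorders
Pleural effusion	Respiratory, thoracic, and mediastinal disorders
Hypoxia	Respiratory, thoracic, and mediastinal disorders
Dyspnoea	Respiratory, thoracic, and mediastinal disorders
Cough	Respiratory, thoracic, and mediastinal disorders
Thrombocytopenia	Blood and lymphatic system disorders
Anaemia	Blood and lymphatic system disorders
Neutropenia	Blood and lymphatic system disorders
Hypothyroidism	Endocrine disorders
Hyperthyroidism	Endocrine disorders
Adrenal insufficiency	Endocrine disorders
Thyroiditis	Endocrine disorders
Thyroid disorder	Endocrine disorders
Myositis	Musculoskeletal and connective tissue disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Myalgia	Musculoskeletal and connective tissue disorders
Renal impairment	Renal and urinary disorders
Hematuria	Renal and urinary disorders
Acute kidney injury	Renal and urinary disorders
Neuropathy peripheral	Nervous system disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Myocarditis	Cardiac disorders
Atrial fibrillation	Cardiac disorders
Cardiac failure	Cardiac disorders
Colitis	Gastrointestinal disorders
Pancreatitis	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Pulmonary embolism	Vascular disorders
Hypertension	Vascular disorders
Hypotension	Vascular disorders
Hepatic function abnormal	Hepatobiliary disorders
Hepatitis	Hepatobiliary disorders
Hepatotoxicity	Hepatobiliary disorders
Oxygen saturation decreased	Investigations
Alanine aminotransferase increased	Investigations
Aspartate aminotransferase increased	Investigations
Blood creatine phosphokinase increased	Investigations
Troponin increased	Investigations
Blood creatinine increased	Investigations
Palmar-plantar erythrodysesthesia syndrome	Skin and subcutaneous tissue disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Cytokine release syndrome	Immune system disorders
Hypersensitivity	Immune system disorders
Infusion related reaction	Injury, poisoning, and procedural complications
Fall	Injury, poisoning, and procedural complications
Pneumonia	Infections and infestations
Urinary tract infection	Infections and infestations
Decreased appetite	Metabolism and nutrition disorders
Dehydration	Metabolism and nutrition disorders
Insomnia	Psychiatric disorders
Confusional state	Psychiatric disorders
Vision blurred	Eye disorders
Uveitis	Eye disorders
Tinnitus	Ear and labyrinth disorders
Vertigo	Ear and labyrinth disorders
Breast pain	Reproductive system and breast disorders
Atrial septal defect	Congenital, familial, and genetic disorders
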