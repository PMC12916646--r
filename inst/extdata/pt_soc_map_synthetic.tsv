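pt	soc
Haematoma	Vascular disorders
Anaemia	Blood and lymphatic system disorders
Haemorrhage	Vascular disorders
Muscle haemorrhage	Vascular disorders
Cerebral haemorrhage	Nervous system disorders
Melaena	Gastrointestinal disorders
Haematemesis	Gastrointestinal disorders
Gastrointestinal haemorrhage	Gastrointestinal disorders
Epistaxis	Respiratory, thoracic and mediastinal disorders
Haematuria	Renal and urinary disorders
Thrombocytopenia	Blood and lymphatic system disorders
Heparin-induced thrombocytopenia	Blood and lymphatic system disorders
Haemoglobin decreased	Investigations
Rash	Skin and subcutaneous tissue disorders
Urticaria	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Skin necrosis	Skin and subcutaneous tissue disorders
Renal failure	Renal and urinary disorders
Coma	Nervous system disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
PT_0001	General disorders and administration site conditions
PT_0002	Nervous system disorders
PT_0003	Gastrointestinal disorders
PT_0004	Investigations
PT_0005	Cardiac disorders
PT_0006	Infections and infestations
PT_0007	Psychiatric disorders
PT_0008	Musculoskeletal and connective tissue disorders
PT_0009	Metabolism and nutrition disorders
PT_0010	Eye disorders
PT_0011	General disorders and administration site conditions
PT_0012	Nervous system disorders
PT_0013	Gastrointestinal disorders
PT_0014	Investigations
PT_0015	Cardiac disorders
PT_0016	Infections and infestations
PT_0017	Psychiatric disorders
PT_0018	Musculoskeletal and connective tissue disorders
PT_0019	Metabolism and nutrition disorders
PT_0020	Eye disorders
PT_0021	General disorders and administration site conditions
PT_0022	Nervous system disorders
PT_0023	Gastrointestinal disorders
PT_0024	Investigations
PT_0025	Cardiac disorders
PT_0026	Infections and infestations
PT_0027	Psychiatric disorders
PT_0028	Musculoskeletal and connective tissue disorders
PT_0029	Metabolism and nutrition disorders
PT_0030	Eye disorders
PT_0031	General disorders and administration site conditions
PT_0032	Nervous system disorders
PT_0033	Gastrointestinal disorders
PT_0034	Investigations
PT_0035	Cardiac disorders
PT_0036	Infections and infestations
PT_0037	Psychiatric disorders
PT_0038	Musculoskeletal and connective tissue disorders
PT_0039	Metabolism and nutrition disorders
PT_0040	Eye disorders
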