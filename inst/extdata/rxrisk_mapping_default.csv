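atc_prefix,category_id,category_name
N07BB,alcohol_dependency,Alcohol dependency
R06A,allergies,Allergies
B01AA,anticoagulants,Anticoagulants
B01AB,anticoagulants,Anticoagulants
B01AE,anticoagulants,Anticoagulants
B01AF,anticoagulants,Anticoagulants
B01AC,antiplatelets,Antiplatelet agents
N05BA,anxiety,Anxiety
N05BE,anxiety,Anxiety
C01AA,arrhythmia,Arrhythmia
C01BA,arrhythmia,Arrhythmia
C01BC,arrhythmia,Arrhythmia
C01BD,arrhythmia,Arrhythmia
G04C,benign_prostatic_hyperplasia,Benign prostatic hyperplasia
N05AN,bipolar_disorder,Bipolar disorder
R03,chronic_airways_disease,Chronic airways disease
C03DA,congestive_heart_failure,Congestive heart failure
N06D,dementia,Dementia
N06A,depression,Depression
A10,diabetes,Diabetes
N03A,epilepsy,Epilepsy
A02BA,gastro_oesophageal_reflux,Gastro-oesophageal reflux disease
A02BC,gastro_oesophageal_reflux,Gastro-oesophageal reflux disease
S01E,glaucoma,Glaucoma
M04A,gout,Gout
J05AF08,hepatitis_b,Hepatitis B
J05AF10,hepatitis_b,Hepatitis B
J05AF11,hepatitis_b,Hepatitis B
J05AP,hepatitis_c,Hepatitis C
J05AE,hiv,HIV
J05AF,hiv,HIV
J05AG,hiv,HIV
J05AR,hiv,HIV
J05AX,hiv,HIV
V03AE,hyperkalaemia,Hyperkalaemia
C10,hyperlipidaemia,Hyperlipidaemia
C02,hypertension,Hypertension
C03A,hypertension,Hypertension
C03B,hypertension,Hypertension
C03C,hypertension,Hypertension
C07,hypertension,Hypertension
C08,hypertension,Hypertension
C09,hypertension,Hypertension
H03B,hyperthyroidism,Hyperthyroidism
H03A,hypothyroidism,Hypothyroidism
A07E,inflammatory_bowel_disease,Inflammatory bowel disease
G04BD,incontinence,Urinary incontinence
C01DA,ischaemic_heart_disease,Ischaemic heart disease (angina)
A06AD11,liver_failure,Liver failure
L01,malignancies,Malignancies
V06D,malnutrition,Malnutrition
N02C,migraine,Migraine
M05B,osteoporosis_pagets,Osteoporosis and Paget's disease
N02A,pain,Pain
M01A,inflammation_arthritis,Inflammation and arthritis
A09AA,pancreatic_insufficiency,Pancreatic insufficiency
N04,parkinsons_disease,Parkinson's disease
D05,psoriasis,Psoriasis
N05A,psychotic_illness,Psychotic illness
C02KX,pulmonary_hypertension,Pulmonary arterial hypertension
B03XA,renal_disease,Chronic renal disease
N07BA,smoking_cessation,Smoking cessation
H02AB,steroid_responsive_disease,Steroid-responsive disease
L04A,transplant,Transplant
J04A,tuberculosis,Tuberculosis
A03A,irritable_bowel_syndrome,Irritable bowel syndrome
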