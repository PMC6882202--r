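disease	disease_name	annual_cases
TCGA-BLCA	Bladder Urothelial Carcinoma	69300
TCGA-BRCA	Invasive Breast Carcinoma	204800
TCGA-CESC	Cervical Squamous Cell Carcinoma	14000
TCGA-COAD	Colon Adenocarcinoma	154840
TCGA-ESCA	Esophageal Adenocarcinoma	4750
TCGA-GBM	Glioblastoma Multiforme	3204
TCGA-HNSC	Head & Neck Squamous Cell Carcinoma	58000
TCGA-KIRC	Renal Clear Cell Carcinoma	57600
TCGA-KIRP	Papillary Renal Cell Carcinoma	8064
TCGA-LAML	Acute Myeloid Leukemia	13500
TCGA-LIHC	Hepatocellular Carcinoma	29700
TCGA-LUSC	Lung Squamous Cell Carcinoma	66000
TCGA-OV	Serous Ovarian Cancer	16800
TCGA-PRAD	Prostate Adenocarcinoma	260000
TCGA-SKCM	Melanoma	75000
TCGA-STAD	Stomach Adenocarcinoma	25000
TCGA-THCA	Thyroid Cancer	46400
TCGA-UCEC	Endometrial Carcinoma	55000
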