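characteristic,level,count
age,under_50,1
age,50_or_over,32
sex,male,27
sex,female,6
primary_site,colon,30
primary_site,rectum,3
gross_morphology,protruded,20
gross_morphology,flat,13
histologic_grade,carcinoma_in_situ,1
histologic_grade,G1,1
histologic_grade,G2,22
histologic_grade,G3,9
mucin_content,nonmucinous,23
mucin_content,mucinous,10
distant_metastasis,pM0,29
distant_metastasis,pM1,4
clinical_stage,0,1
clinical_stage,I,3
clinical_stage,II,12
clinical_stage,III,13
clinical_stage,IV,4
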