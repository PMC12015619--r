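patient_id,hospital_id,fiscal_year,age,sex,icd10,bun,spo2,orientation_disturbance,sbp,immunodeficiency,prior_hosp_90d,admit_from_home,admit_from_nursing_home,icu,ventilator,tube_feeding,chf,hypertension,copd,diabetes,dementia,cerebrovascular,renal,rheumatic,cancer,pulm_circ,surgery_before_treatment,abx_within_48h,broad_spectrum_use
P01,H1,FY2018,80,1,J18.9,25,92,0,130,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,1
P02,H1,FY2018,64,0,J18.9,18,95,0,140,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0
P03,H1,FY2019,65,1,J15.0,30,88,1,85,0,1,0,1,0,0,0,0,0,1,0,1,0,0,0,0,0,0,1,1
P04,H1,FY2018,75,0,A41.9,22,93,0,120,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,0
P05,H1,FY2019,75,1,J13,15,96,0,135,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0
P06,H1,FY2018,90,0,J16.5,28,91,0,110,0,0,0,1,0,0,1,1,0,0,0,1,0,0,0,0,0,1,1,0
P07,H2,FY2018,70,1,J14,,94,0,125,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,1,1
P08,H2,FY2019,85,0,J17.2,24,,1,100,0,1,0,0,1,1,0,0,1,0,0,1,0,1,0,0,0,0,1,1
P09,H2,FY2018,77,0,J18.0,19,97,0,150,0,0,1,0,0,0,0,0,1,0,1,0,0,0,0,0,0,0,1,0
P10,H2,FY2019,66,1,J15.9,35,89,0,90,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,0,1,1
P11,H2,FY2018,72,0,J18.1,20,95,0,,0,0,1,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0
P12,H2,FY2019,95,1,J13,40,85,1,80,0,1,0,1,0,0,1,0,0,0,1,1,0,1,0,0,0,0,1,1
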