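column,kind,units,aggregation,description
patient_id,id,,,unique patient identifier
hour,id,hours,,hour index; 0 is the first glucose measurement after ICU admission
glucose,dynamic,mg/dL,mean,blood glucose
insulin,dynamic,units,sum,regular insulin administered during the hour (the action)
heart_rate,dynamic,beats/min,mean,heart rate
resp_rate,dynamic,breaths/min,mean,respiratory rate
sbp,dynamic,mmHg,mean,systolic blood pressure
dbp,dynamic,mmHg,mean,diastolic blood pressure
map,dynamic,mmHg,mean,mean arterial pressure
temp_c,dynamic,degC,mean,core temperature
spo2,dynamic,%,mean,oxygen saturation
wbc,dynamic,1e9/L,mean,white blood cell count
creatinine,dynamic,mg/dL,mean,serum creatinine
lactate,dynamic,mmol/L,mean,serum lactate
potassium,dynamic,mmol/L,mean,serum potassium
hemoglobin,dynamic,g/dL,mean,hemoglobin
sofa,dynamic,score,mean,Sequential Organ Failure Assessment score
on_vasopressor,dynamic,0/1,mean,any vasopressor infusion running
vasopressor_dose,dynamic,ug/kg/min,mean,norepinephrine-equivalent vasopressor dose
mech_vent,dynamic,0/1,mean,mechanical ventilation
age,static,years,,age at admission
sex,static,0/1,,1 = male
weight,static,kg,,admission weight
bmi,static,kg/m2,,body mass index
diabetes_type,static,0/1/2,,0 none; 1 type 1; 2 type 2
surgery_cabg,static,0/1,,coronary artery bypass graft
surgery_valve,static,0/1,,valve repair/replacement
htn,static,0/1,,history of hypertension
chf,static,0/1,,congestive heart failure
copd,static,0/1,,chronic obstructive pulmonary disease
esrd,static,0/1,,end-stage renal disease
prior_mi,static,0/1,,prior myocardial infarction
elixhauser,static,score,,Elixhauser comorbidity index
died_within_24h,flag,0/1,,exclusion: died within the first 24 h
ambiguous_meds,flag,0/1,,exclusion: medication doses not resolvable
no_glucose_3h,flag,0/1,,exclusion: no glucose within the first three hours
other_insulin,flag,0/1,,exclusion: received other short-acting insulins
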