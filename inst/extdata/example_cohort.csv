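patient_id,tumor_class,age_years,sex,distance_km,size_clinical_mm,size_radiological_mm,depth,signs,imaging_performed,imaging_pattern,real_management,observed_interval_months,histology
EX01,nonbenign,54,female,35,9,9,superficial,,TRUE,homogeneous_other,referral_expert,12,dermatofibrosarcoma
EX02,nonbenign,67,male,120,110,120,deep_or_mixed,growth|pain,TRUE,heterogeneous_suspicious,surgery_nonexpert,14,leiomyosarcoma
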