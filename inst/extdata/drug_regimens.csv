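therapy_id,national_code,presentation,pack_price,active_ingredient,dose_per_standard_unit_mg,cost_per_standard_unit,daily_dose_mg,standard_units_per_day,annual_cost_printed
apo_go,74.401,5 jeringas 10 mL,"100,00",apomorfina 5 mg/mL,"50","20","74,68","2","14.600"
dacepton,79.174,1 ampolla 20 mL,"40,00",apomorfina 5 mg/mL,"100","40","74,68","0,75","10.950"
duodopa,66.547,7 cartuchos 100 mL,"756,00",levodopa 20 mg/mL + carbidopa 5 mg/mL,"2.000","108","1.300","1","39.420"
foslevodopa,88.677,7 viales 10 mL,"771,12",foslevodopa 240 mg/mL + foscarbidopa 12 mg/mL,"2.400","110,16","1.621","1","40.208"
lecigon,86.092,7 cartuchos 47 mL,"756,00",levodopa 20 mg/mL + carbidopa 5 mg/mL + entacapona 20 mg/mL,"940","108","1.164","1,5","59.130"
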