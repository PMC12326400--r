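therapy_id,life_years,qalys
apo_go,6.385,2.885
dacepton,6.385,2.885
percept_pc,6.495,2.800
percept_rc,6.495,2.800
duodopa,7.055,3.120
foslevodopa,8.151,3.605
lecigon,7.055,3.120
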