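therapy_id,device_group,brand_name,ace_printed,acu_printed
apo_go,Apomorfina,Apo-Go,"12.473","27.615"
dacepton,Apomorfina,Dacepton,"9.387","20.782"
lecigon,Levodopa + Carbidopa + Entacapona,Lecigon,"46.047","104.000"
duodopa,Levodopa + Carbidopa,Duodopa,"30.953","69.909"
foslevodopa,Foslevodopa + Foscarbidopa,Foslevodopa,"26.808","60.319"
percept_pc,Estimulacion cerebral profunda (DBS),Percept PC,"10.732","24.874"
percept_rc,Estimulacion cerebral profunda (DBS),Percept RC,"13.303","30.833"
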