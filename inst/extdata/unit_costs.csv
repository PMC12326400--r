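item_id,label,unit_cost,source_year
first_neuro_consult,Primera consulta neurologia,"117,81",2023
neuro_review,Revision neurologia,"58,90",2023
first_neurosurgery_consult,Primera consulta neurocirugia,"153,86",2023
neurosurgery_review,Revision neurocirugia,"73,93",2023
psychology_assessment,Valoracion psicologia,"53,51",2023
neurology_admission,Ingreso neurologia,"466,50",2023
apomorphine_test,Test apomorfina,"147,66",2023
neurosurgery_admission,Ingreso neurocirugia,"635,65",2023
peg_procedure,Gastrostomia endoscopica percutanea (PEG),"4.367,00",2023
lab_panel,Analitica,"24,96",2023
ekg,Electrocardiograma,"16,23",2023
chest_xray,Rx torax,"9,23",2023
abdominal_xray,Rx abdomen,"9,23",2023
cranial_ct,TAC craneo,"55,38",2023
cranial_mri,RMN craneo,"119,99",2023
control_ct,TAC control,"55,38",2023
control_mri,RMN control,"119,99",2023
anesthesia_assessment,Valoracion anestesia,"89,74",2023
neurosurgery_procedure,Procedimiento quirurgico neurocirugia,"23.132,00",2023
dbs_implant_pc,DBS primer implante PC,"24.758,00",2023
dbs_replacement_pc,Recambio PC,"16.078,00",2023
dbs_implant_rc,DBS primer implante RC,"33.110,00",2023
dbs_replacement_rc,Recambio RC,"24.430,00",2023
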