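code_prefix,hac_group_id,group_name
L890,1,Pressure injury
L891,1,Pressure injury
L892,1,Pressure injury
L893,1,Pressure injury
S720,2,Falls resulting in fracture or intracranial injury
S721,2,Falls resulting in fracture or intracranial injury
S722,2,Falls resulting in fracture or intracranial injury
S060,2,Falls resulting in fracture or intracranial injury
S062,2,Falls resulting in fracture or intracranial injury
T814,3,Healthcare-associated infection
J22,3,Healthcare-associated infection
N390,3,Healthcare-associated infection
T835,3,Healthcare-associated infection
T81,4,Surgical complications requiring unplanned return to theatre
T810,4,Surgical complications requiring unplanned return to theatre
T812,4,Surgical complications requiring unplanned return to theatre
T818,4,Surgical complications requiring unplanned return to theatre
J80,6,Respiratory complications
J960,6,Respiratory complications
J690,6,Respiratory complications
J681,6,Respiratory complications
I260,7,Venous thromboembolism
I269,7,Venous thromboembolism
I801,7,Venous thromboembolism
I802,7,Venous thromboembolism
I822,7,Venous thromboembolism
N170,8,Renal failure
N178,8,Renal failure
N179,8,Renal failure
K920,9,Gastrointestinal bleeding
K921,9,Gastrointestinal bleeding
K922,9,Gastrointestinal bleeding
K250,9,Gastrointestinal bleeding
T380,10,Medication complications
T405,10,Medication complications
T455,10,Medication complications
T885,10,Medication complications
F050,11,Delirium
F058,11,Delirium
F059,11,Delirium
R32,12,Incontinence
R150,12,Incontinence
N393,12,Incontinence
N394,12,Incontinence
E150,13,Endocrine complications
E160,13,Endocrine complications
E162,13,Endocrine complications
E870,13,Endocrine complications
I460,14,Cardiac complications
I461,14,Cardiac complications
I469,14,Cardiac complications
I472,14,Cardiac complications
I490,14,Cardiac complications
O702,15,Third and fourth degree perineal laceration during delivery
O703,15,Third and fourth degree perineal laceration during delivery
P100,16,Neonatal birth trauma
P110,16,Neonatal birth trauma
P134,16,Neonatal birth trauma
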