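file,column,type,unit,description
panel.csv,patient_id,integer,,stable patient identifier within the cohort
panel.csv,wave,integer,occasion,measurement occasion 1..4
panel.csv,week,integer,weeks,weeks since hospital discharge (1 3 6 12)
panel.csv,tsk_total,integer or empty,points,kinesiophobia questionnaire total in 13..52; empty when missing
panel.csv,pa_light,real,minutes/day,light-intensity activity (below 3 MET and above the sedentary cutpoint)
panel.csv,pa_moderate,real,minutes/day,moderate-intensity activity (3 to 6 MET inclusive)
panel.csv,pa_heavy,real,minutes/day,heavy-intensity activity (above 6 MET)
panel.csv,pa_total,real,minutes/day,light + moderate + heavy
panel.csv,tsk_missing,logical,,questionnaire missingness mask (TRUE = deleted cell)
panel.csv,pa_missing,logical,,activity missingness mask
items.csv,patient_id,integer,,patient identifier
items.csv,wave,integer,occasion,measurement occasion 1..4
items.csv,item_1..item_13,integer or empty,points,questionnaire item scores in 1..4; sum equals tsk_total when observed
items.csv,missing,logical,,questionnaire missingness mask for the whole wave record
epochs.csv,patient_id,integer,,patient identifier
epochs.csv,day,integer,days,wear day index (1 = discharge day)
epochs.csv,timestamp,ISO-8601 datetime,UTC,epoch start time
epochs.csv,met,real,multiples of resting metabolic rate,epoch MET value
epochs.csv,missing,logical,,epoch-level accelerometer missingness mask
flow.json,stage,string,,exclusion-flow stage label
flow.json,removed,integer,patients,patients removed at the stage
flow.json,remaining,integer,patients,patients remaining after the stage
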