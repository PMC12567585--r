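column,type,encoding,description
subject_id,id,string,Unique participant identifier
sex,categorical,0 = male; 1 = female,Child sex
age,numeric,years,Age at enrolment (7-13)
bmi,numeric,kg/m^2,Body mass index
grade,ordinal,1-7,School grade level
health_state,ordinal,1 = poor; 2 = good; 3 = very good,Self/parent-reported health status
diet_state,ordinal,1 = poor; 2 = good; 3 = very good,Dietary habit rating
parental_education,ordinal,1 = poor; 2 = moderate; 3 = good,Parental education level
snap_01..snap_09,ordinal,0-3,SNAP-IV inattention items (0 = not at all .. 3 = very much)
snap_10..snap_18,ordinal,0-3,SNAP-IV hyperactivity/impulsivity items
snap_19..snap_26,ordinal,0-3,SNAP-IV oppositional defiance items
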