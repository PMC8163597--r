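student_id,cohort_id,year_of_study,staff_id,patient_id,restoration_id,stage_id,di,quadrant,tooth,surface,material,staff_difficult_flag
S001,cohort1,5,ST01,P01,R001,stage01,5,1,6,approximal_posterior,composite,false
S001,cohort1,5,ST01,P01,R001,stage02,4,1,6,approximal_posterior,composite,false
S001,cohort1,5,ST01,P01,R001,stage03,6,1,6,approximal_posterior,composite,false
S001,cohort1,5,ST02,P01,R002,stage01,3,3,5,occlusal_surface,composite,false
S001,cohort1,5,ST02,P01,R002,stage02,5,3,5,occlusal_surface,composite,false
S001,cohort1,5,ST02,P01,R002,stage03,5,3,5,occlusal_surface,composite,false
S001,cohort1,5,ST01,P02,R003,stage01,5,2,3,smooth_surface,composite,false
S001,cohort1,5,ST01,P02,R003,stage02,6,2,3,smooth_surface,composite,false
S001,cohort1,5,ST01,P02,R003,stage03,5,2,3,smooth_surface,composite,false
S001,cohort1,5,ST03,P02,R004,stage01,6,4,2,approximal_anterior,composite,false
S001,cohort1,5,ST03,P02,R004,stage02,5,4,2,approximal_anterior,composite,false
S001,cohort1,5,ST03,P02,R004,stage03,5,4,2,approximal_anterior,composite,false
S001,cohort1,5,ST02,P03,R005,stage01,6,1,1,incisal_edge,composite,false
S001,cohort1,5,ST02,P03,R005,stage02,6,1,1,incisal_edge,composite,false
S001,cohort1,5,ST02,P03,R005,stage03,6,1,1,incisal_edge,composite,false
S001,cohort1,5,ST01,P03,R006,stage01,6,2,7,occlusal_surface,composite,false
S001,cohort1,5,ST01,P03,R006,stage02,6,2,7,occlusal_surface,composite,false
S001,cohort1,5,ST01,P03,R006,stage03,6,2,7,occlusal_surface,composite,false
S001,cohort1,5,ST04,P04,R007,stage01,4,3,4,approximal_posterior,composite,false
S001,cohort1,5,ST04,P04,R007,stage02,4,3,4,approximal_posterior,composite,false
S001,cohort1,5,ST04,P04,R007,stage03,5,3,4,approximal_posterior,composite,false
S001,cohort1,5,ST02,P04,R008,stage01,5,4,8,smooth_surface,composite,false
S001,cohort1,5,ST02,P04,R008,stage02,5,4,8,smooth_surface,composite,false
S001,cohort1,5,ST02,P04,R008,stage03,6,4,8,smooth_surface,composite,false
S001,cohort1,5,ST03,P05,R009,stage01,6,1,5,occlusal_surface,composite,false
S001,cohort1,5,ST03,P05,R009,stage02,4,1,5,occlusal_surface,composite,false
S001,cohort1,5,ST03,P05,R009,stage03,5,1,5,occlusal_surface,composite,false
S001,cohort1,5,ST01,P05,R010,stage01,6,2,3,approximal_anterior,composite,true
S001,cohort1,5,ST01,P05,R010,stage02,6,2,3,approximal_anterior,composite,true
S001,cohort1,5,ST01,P05,R010,stage03,6,2,3,approximal_anterior,composite,true
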