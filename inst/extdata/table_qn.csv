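subject,group,process,session,qn
S1,trained,calibration,non_feedback,3.67
S2,trained,calibration,non_feedback,3.00
S3,trained,calibration,non_feedback,3.00
S4,trained,calibration,non_feedback,3.83
S5,trained,calibration,non_feedback,3.00
S6,untrained,calibration,non_feedback,2.28
S7,untrained,calibration,non_feedback,2.56
S8,untrained,calibration,non_feedback,3.00
S9,untrained,calibration,non_feedback,2.06
S10,untrained,calibration,non_feedback,3.00
S1,trained,calibration,trial_feedback,3.00
S2,trained,calibration,trial_feedback,3.00
S3,trained,calibration,trial_feedback,3.00
S4,trained,calibration,trial_feedback,3.83
S5,trained,calibration,trial_feedback,3.00
S6,untrained,calibration,trial_feedback,2.00
S7,untrained,calibration,trial_feedback,2.72
S8,untrained,calibration,trial_feedback,3.00
S9,untrained,calibration,trial_feedback,1.44
S10,untrained,calibration,trial_feedback,3.00
S1,trained,testing,non_feedback,3.25
S2,trained,testing,non_feedback,3.25
S3,trained,testing,non_feedback,3.58
S4,trained,testing,non_feedback,4.25
S5,trained,testing,non_feedback,3.00
S6,untrained,testing,non_feedback,2.58
S7,untrained,testing,non_feedback,2.75
S8,untrained,testing,non_feedback,3.00
S9,untrained,testing,non_feedback,2.00
S10,untrained,testing,non_feedback,3.00
S1,trained,testing,trial_feedback,3.00
S2,trained,testing,trial_feedback,3.25
S3,trained,testing,trial_feedback,3.08
S4,trained,testing,trial_feedback,4.50
S5,trained,testing,trial_feedback,3.00
S6,untrained,testing,trial_feedback,2.00
S7,untrained,testing,trial_feedback,2.67
S8,untrained,testing,trial_feedback,3.00
S9,untrained,testing,trial_feedback,1.33
S10,untrained,testing,trial_feedback,3.00
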