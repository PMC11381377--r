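subject,group,session,cd
S1,trained,non_feedback,0.46
S2,trained,non_feedback,0.89
S3,trained,non_feedback,1.19
S4,trained,non_feedback,0.46
S5,trained,non_feedback,1.18
S6,untrained,non_feedback,0.89
S7,untrained,non_feedback,0.78
S8,untrained,non_feedback,0.50
S9,untrained,non_feedback,0.56
S10,untrained,non_feedback,0.98
S1,trained,trial_feedback,0.51
S2,trained,trial_feedback,1.26
S3,trained,trial_feedback,0.69
S4,trained,trial_feedback,0.59
S5,trained,trial_feedback,1.31
S6,untrained,trial_feedback,0.46
S7,untrained,trial_feedback,0.49
S8,untrained,trial_feedback,0.88
S9,untrained,trial_feedback,0.60
S10,untrained,trial_feedback,0.78
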