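session,stage,slot,mean_ca_pct
non_feedback,first_two,1,49
non_feedback,first_two,2,53
trial_feedback,first_two,1,59
trial_feedback,first_two,2,63
non_feedback,last_two,1,46
non_feedback,last_two,2,56
trial_feedback,last_two,1,66
trial_feedback,last_two,2,60
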