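session,stage,n_benchmark
non_feedback,first_two,5
trial_feedback,first_two,8
non_feedback,last_two,2
trial_feedback,last_two,6
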