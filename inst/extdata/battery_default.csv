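test,domain,orientation,pop_mean,pop_sd
letter_number_sequencing,working_memory,higher_better,11,3
stroop_interference_s,executive,lower_better,110,22
trail_making_a_s,psychomotor_speed,lower_better,35,11
symbol_digit_correct,information_processing,higher_better,52,9
digit_vigilance_hits,attention,higher_better,420,40
word_list_delayed_recall,verbal_memory,higher_better,9,3
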