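item,group,value
score_bin,0,12
score_bin,14.29,18
score_bin,28.57,18
score_bin,42.86,17
score_bin,57.14,6
score_bin,71.43,17
score_bin,85.71,26
score_bin,100,9
patients,male,27
patients,female,14
cases,male,81
cases,female,42
enrollment,approached,238
enrollment,consented,79
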