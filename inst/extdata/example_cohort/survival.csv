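"subject_id","time","event","age"
"p01",14.2,1,61
"p02",31.5,0,58
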