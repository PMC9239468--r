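subject_id,image_id,xmin,xmax,ymin,ymax
p01,a,0,400,0,300
p01,b,0,400,0,300
p02,a,0,400,0,300
p02,b,0,400,0,300
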