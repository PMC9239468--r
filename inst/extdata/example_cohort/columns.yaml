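"x": "x"
"y": "y"
type: cell_type
subject: subject_id
image: image_id
marks:
  - mhcii
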