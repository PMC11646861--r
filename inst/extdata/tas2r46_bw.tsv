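segment	start	end	anchor_label	anchor_residue
TM3	82	112	3.50	106
TM5	184	212	5.68	205
TM6	220	250	6.48	241
TM7	256	282	7.39	265
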