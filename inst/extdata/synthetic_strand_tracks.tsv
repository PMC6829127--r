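model	start	end
synthA	17	20
synthA	31	36
synthA	39	42
synthB	15	21
synthB	30	36
synthC	3	10
synthC	18	26
synthC	33	38
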