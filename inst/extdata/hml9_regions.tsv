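region	start	end
LTR5	1	587
gag	758	2548
pro	2548	3435
pol	3411	6060
env	5975	8020
LTR3	8022	8608
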