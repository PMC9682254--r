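variable	level	n
Sex	Female	17
Sex	Male	44
Histology	Adenocarcinoma	27
Histology	Squamous cell carcinoma	32
Histology	Adenosquamous carcinoma	1
Histology	Non-small cell lung cancer	1
Regimen	Combination	42
Regimen	Monotherapy	19
Checkpoint inhibitor	Pembrolizumab	19
Checkpoint inhibitor	Camrelizumab	13
Checkpoint inhibitor	Nivolumab	9
Checkpoint inhibitor	Sintilimab	8
Checkpoint inhibitor	Tislelizumab	5
Checkpoint inhibitor	Others	7
PD-L1	TPS < 1%	18
PD-L1	TPS >= 1%	30
PD-L1	Unknown	13
Response	PD	11
Response	PR	17
Response	SD	33
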