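ancestry	n_studies	n_cases	n_controls
EastAsian	7	9867	12870
European	5	4555	12932
SouthAsian	4	6196	13775
AfricanAmerican	1	631	2526
MexicanAmerican	1	837	436
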