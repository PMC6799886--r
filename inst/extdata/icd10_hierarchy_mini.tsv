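code3	block	chapter
E10	E10-E14	IV
E11	E10-E14	IV
E66	E65-E68	IV
E78	E70-E90	IV
I10	I10-I15	IX
I20	I20-I25	IX
I21	I20-I25	IX
I25	I20-I25	IX
I50	I30-I52	IX
I63	I60-I69	IX
J45	J40-J47	X
M10	M05-M14	XIII
N39	N30-N39	XIV
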