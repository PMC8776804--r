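julian_day	fraction	name	kind	norm_coverage	host
102	10um	Freya	phage	53.8	Polaribacter
102	10um	Freya_relatives	relative	63.3	Polaribacter
102	10um	Danklef	phage	10.4	Polaribacter
102	10um	Danklef_relatives	relative	45.8	Polaribacter
102	10um	Ingeline	phage	0.7	NA
102	10um	Ingeline_relatives	relative	0.8	NA
102	10um	Polaribacter	bacterium	0.14	NA
102	10um	Olleya	bacterium	0.05	NA
116	10um	Polaribacter	bacterium	0.06	NA
116	10um	Olleya	bacterium	0.03	NA
122	0.2um	Polaribacter	bacterium	0.07	NA
122	0.2um	Olleya	bacterium	0.05	NA
128	3um	Harreka	phage	1.8	NA
128	3um	Harreka_relatives	relative	5.7	NA
142	10um	Freya_relatives	relative	0.04	Polaribacter
142	10um	Danklef_relatives	relative	0.03	Polaribacter
142	10um	Leef_relatives	relative	0.02	Polaribacter
142	10um	Polaribacter	bacterium	0.46	NA
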