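distance_um	multiplicity	class
14.7	1	unidirectional
74.4	7	unidirectional
75.8	14	unidirectional
117.7	1	unidirectional
91.3	4	unidirectional
134	6	unidirectional
162.6	1	unidirectional
73.3	1	bidirectional
75.6	10	bidirectional
86.9	23	bidirectional
97	10	bidirectional
184.6	3	bidirectional
157	10	bidirectional
141.8	5	bidirectional
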