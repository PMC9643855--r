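rsid	class	n0	n1	n2
rs1800587	control	486	201	23
rs1800587	case	127	78	16
rs1800796	control	195	353	162
rs1800796	case	97	98	26
rs361525	control	642	63	5
rs361525	case	164	17	40
rs1800629	control	634	72	4
rs1800629	case	154	21	46
rs2069705	control	224	349	137
rs2069705	case	86	81	54
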