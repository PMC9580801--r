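# Main vs recovery period community-type counts for the treated arms.
group	period	ct_label	n
HEC	main	A-H	41
HEC	main	Ps	11
HEC	main	Ec	2
HEC	recovery	A-H	6
HEC	recovery	Ps	8
HEC	recovery	A-H-Ps	2
N9	main	A-H	30
N9	main	Ps	1
N9	main	H	17
N9	main	Cy	5
N9	main	U	1
N9	recovery	A-H	16
BZK	main	A-H	20
BZK	main	Ps	9
BZK	main	Ec	2
BZK	main	Cy	20
BZK	main	U	3
BZK	recovery	A-H	9
BZK	recovery	Ps	1
BZK	recovery	Ec	1
BZK	recovery	Cy	2
BZK	recovery	U	1
BZK	recovery	A-H-Ps	2
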