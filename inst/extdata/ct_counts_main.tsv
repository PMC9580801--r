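# Main-period (days 1-9) community-type counts per study arm.
# "Pre-Dose" are baseline day-1 samples across all arms; "Sham" are
# untreated swab-only controls. The pooled no-treatment arm is the sum of
# the Pre-Dose and Sham rows.
group	ct_label	n
Pre-Dose	A-H	26
Pre-Dose	Ps	6
Pre-Dose	Ec	5
Sham	A-H	11
Sham	Ps	3
HEC	A-H	41
HEC	Ps	11
HEC	Ec	2
N9	A-H	30
N9	Ps	1
N9	H	17
N9	Cy	5
N9	U	1
BZK	A-H	20
BZK	Ps	9
BZK	Ec	2
BZK	Cy	20
BZK	U	3
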