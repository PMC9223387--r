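id	system	expected	uptakes	secretions
co2_from_glc_aerobic	energy	feasible	glc:10;o2:100	co2:1
lactate_from_glc_anaerobic	energy	feasible	glc:10	lac:0.1
ala_synthesis_from_glc_nh3	amino acid	feasible	glc:10;nh3:10;o2:100	ala:0.1;co2:0
gln_synthesis_from_glc_nh3	amino acid	feasible	glc:10;nh3:10;o2:100	gln:0.1;co2:0
gly_synthesis_from_glc_nh3	amino acid	feasible	glc:10;nh3:10;o2:100	gly:0.1;co2:0
lys_synthesis_from_glc_nh3	amino acid	infeasible	glc:10;nh3:10;o2:100	lys:0.1;co2:0
met_synthesis_from_glc_nh3	amino acid	infeasible	glc:10;nh3:10;o2:100	met:0.1;co2:0
trp_synthesis_from_glc_nh3	amino acid	infeasible	glc:10;nh3:10;o2:100	trp:0.1;co2:0
his_synthesis_from_glc_nh3	amino acid	infeasible	glc:10;nh3:10;o2:100	his:0.1;co2:0
thr_synthesis_from_glc_nh3	amino acid	infeasible	glc:10;nh3:10;o2:100	thr:0.1;co2:0
urea_from_arginine	nitrogen	feasible	arg:10;o2:100	urea:0.1;co2:0;nh3:0
urea_from_ammonia	nitrogen	infeasible	nh3:10;glc:10;o2:100	urea:0.1;co2:0
nh3_disposal_from_aa	nitrogen	feasible	lys:10;o2:100	nh3:0.1;co2:0
lipid_from_choline	lipid	feasible	chol:10;glc:10;o2:100;pi:10	lipid_c:0.1;co2:0;nh3:0
lipid_without_choline	lipid	infeasible	glc:10;o2:100;pi:10	lipid_c:0.1;co2:0;nh3:0
ntp_synthesis	nucleotide	feasible	glc:10;nh3:10;pi:10;o2:100	ntp_c:0.1;co2:0
glycan_synthesis	glycan	infeasible	glc:10;o2:100	glycan_c:0.1
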