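id	name	compartment	charge	formula	is_pmf
glc_c	D-glucose	cytosolic	0	C6H12O6	FALSE
g6p_c	glucose 6-phosphate	cytosolic	-2		FALSE
f6p_c	fructose 6-phosphate	cytosolic	-2		FALSE
fdp_c	fructose 1,6-bisphosphate	cytosolic	-4		FALSE
dhap_c	dihydroxyacetone phosphate	cytosolic	-2		FALSE
g3p_c	glyceraldehyde 3-phosphate	cytosolic	-2		FALSE
13dpg_c	1,3-bisphosphoglycerate	cytosolic	-4		FALSE
3pg_c	3-phosphoglycerate	cytosolic	-3		FALSE
2pg_c	2-phosphoglycerate	cytosolic	-3		FALSE
pep_c	phosphoenolpyruvate	cytosolic	-3		FALSE
pep_m	phosphoenolpyruvate	mitochondrial	-3		FALSE
pyr_c	pyruvate	cytosolic	-1	C3H3O3	FALSE
pyr_m	pyruvate	mitochondrial	-1	C3H3O3	FALSE
lac_c	(S)-lactate	cytosolic	-1	C3H5O3	FALSE
glyc_c	glycerol	cytosolic	0	C3H8O3	FALSE
glyc3p_c	glycerol 3-phosphate	cytosolic	-2		FALSE
cit_m	citrate	mitochondrial	-3	C6H5O7	FALSE
icit_m	isocitrate	mitochondrial	-3	C6H5O7	FALSE
akg_c	2-oxoglutarate	cytosolic	-2	C5H4O5	FALSE
akg_m	2-oxoglutarate	mitochondrial	-2	C5H4O5	FALSE
succoa_m	succinyl-CoA	mitochondrial	-5		FALSE
succ_m	succinate	mitochondrial	-2	C4H4O4	FALSE
fum_c	fumarate	cytosolic	-2	C4H2O4	FALSE
fum_m	fumarate	mitochondrial	-2	C4H2O4	FALSE
mal_c	(S)-malate	cytosolic	-2	C4H4O5	FALSE
mal_m	(S)-malate	mitochondrial	-2	C4H4O5	FALSE
oaa_c	oxaloacetate	cytosolic	-2	C4H2O5	FALSE
oaa_m	oxaloacetate	mitochondrial	-2	C4H2O5	FALSE
accoa_m	acetyl-CoA	mitochondrial	-4		FALSE
aacoa_m	acetoacetyl-CoA	mitochondrial	-4		FALSE
coa_c	coenzyme A	cytosolic	-4		FALSE
coa_m	coenzyme A	mitochondrial	-4		FALSE
bhb_c	(R)-3-hydroxybutanoate	cytosolic	-1	C4H7O3	FALSE
bhb_m	(R)-3-hydroxybutanoate	mitochondrial	-1	C4H7O3	FALSE
acac_c	acetoacetate	cytosolic	-1	C4H5O3	FALSE
acac_m	acetoacetate	mitochondrial	-1	C4H5O3	FALSE
hdca_c	hexadecanoate	cytosolic	-1	C16H31O2	FALSE
hdca_m	hexadecanoate	mitochondrial	-1	C16H31O2	FALSE
pmtcoa_c	palmitoyl-CoA	cytosolic	-4		FALSE
pmtcoa_m	palmitoyl-CoA	mitochondrial	-4		FALSE
crn_c	L-carnitine	cytosolic	0		FALSE
crn_m	L-carnitine	mitochondrial	0		FALSE
pmtcrn_c	palmitoyl-carnitine	cytosolic	0		FALSE
pmtcrn_m	palmitoyl-carnitine	mitochondrial	0		FALSE
ala_c	L-alanine	cytosolic	0	C3H7NO2	FALSE
ala_m	L-alanine	mitochondrial	0	C3H7NO2	FALSE
asp_c	L-aspartate	cytosolic	-1	C4H6NO4	FALSE
asp_m	L-aspartate	mitochondrial	-1	C4H6NO4	FALSE
glu_c	L-glutamate	cytosolic	-1	C5H8NO4	FALSE
glu_m	L-glutamate	mitochondrial	-1	C5H8NO4	FALSE
gln_c	L-glutamine	cytosolic	0	C5H10N2O3	FALSE
gln_m	L-glutamine	mitochondrial	0	C5H10N2O3	FALSE
gly_c	glycine	cytosolic	0	C2H5NO2	FALSE
gly_m	glycine	mitochondrial	0	C2H5NO2	FALSE
nh3_c	ammonia	cytosolic	0	H3N	FALSE
nh3_m	ammonia	mitochondrial	0	H3N	FALSE
nad_c	NAD+	cytosolic	-1		FALSE
nad_m	NAD+	mitochondrial	-1		FALSE
nadh_c	NADH	cytosolic	-2		FALSE
nadh_m	NADH	mitochondrial	-2		FALSE
nadp_m	NADP+	mitochondrial	-3		FALSE
nadph_m	NADPH	mitochondrial	-4		FALSE
atp_c	ATP	cytosolic	-4		FALSE
atp_m	ATP	mitochondrial	-4		FALSE
adp_c	ADP	cytosolic	-3		FALSE
adp_m	ADP	mitochondrial	-3		FALSE
amp_c	AMP	cytosolic	-2		FALSE
gtp_m	GTP	mitochondrial	-4		FALSE
gdp_m	GDP	mitochondrial	-3		FALSE
pi_c	orthophosphate	cytosolic	-2		FALSE
pi_m	orthophosphate	mitochondrial	-2		FALSE
ppi_c	pyrophosphate	cytosolic	-3		FALSE
q10_m	ubiquinone	mitochondrial	0		FALSE
q10h2_m	ubiquinol	mitochondrial	0		FALSE
etfox_m	ETF (oxidised)	mitochondrial	0		FALSE
etfrd_m	ETF (reduced)	mitochondrial	0		FALSE
ficytc_m	ferricytochrome c	mitochondrial	3		FALSE
focytc_m	ferrocytochrome c	mitochondrial	2		FALSE
o2s_m	superoxide	mitochondrial	-1		FALSE
h2o2_m	hydrogen peroxide	mitochondrial	0	H2O2	FALSE
o2_c	oxygen	cytosolic	0	O2	FALSE
o2_m	oxygen	mitochondrial	0	O2	FALSE
co2_c	carbon dioxide	cytosolic	0	CO2	FALSE
co2_m	carbon dioxide	mitochondrial	0	CO2	FALSE
h2o_c	water	cytosolic	0	H2O	FALSE
h2o_m	water	mitochondrial	0	H2O	FALSE
pmf_c	proton motive force	cytosolic	0		TRUE
pmf_m	proton motive force	mitochondrial	0		TRUE
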