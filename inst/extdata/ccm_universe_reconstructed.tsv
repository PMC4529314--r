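# ccmspace reaction universe v1
# E. coli central carbon metabolism, reconstructed from the published core
# model: ethanol branch removed, aconitase A/B merged, ATP maintenance
# bound relaxed so ATPase is a variable internal reaction.
# metabolites: 13dpg_c,2pg_c,3pg_c,6pgc_c,6pgl_c,ac_c,ac_e,acald_c,acald_e,accoa_c,actp_c,adp_c,akg_c,akg_e,amp_c,atp_c,cit_c,co2_c,co2_e,coa_c,dhap_c,e4p_c,f6p_c,fdp_c,for_c,for_e,fru_e,fum_c,fum_e,g3p_c,g6p_c,glc__D_e,gln__L_c,gln__L_e,glu__L_c,glu__L_e,glx_c,h2o_c,h2o_e,h_c,h_e,icit_c,lac__D_c,lac__D_e,mal__L_c,mal__L_e,nad_c,nadh_c,nadp_c,nadph_c,nh4_c,nh4_e,o2_c,o2_e,oaa_c,pep_c,pi_c,pi_e,pyr_c,pyr_e,q8_c,q8h2_c,r5p_c,ru5p__D_c,s7p_c,succ_c,succ_e,succoa_c,xu5p__D_c
# precursors: g6p_c,f6p_c,r5p_c,e4p_c,g3p_c,3pg_c,pep_c,pyr_c,accoa_c,akg_c,oaa_c,glu__L_c,gln__L_c
# cofactor_pair: ME1|ME2
# cofactor_pair: THD2|NADTRHD
# cofactor_pair: ATPM|ATPS4r
id	equation	reversible	lb	ub	class
ACALD	acald_c + coa_c + nad_c <-> accoa_c + h_c + nadh_c	TRUE	-1000	1000	internal
ACALDt	acald_e <-> acald_c	TRUE	-1000	1000	transport
ACKr	ac_c + atp_c <-> actp_c + adp_c	TRUE	-1000	1000	internal
ACt2r	ac_e + h_e <-> ac_c + h_c	TRUE	-1000	1000	transport
ADK1	amp_c + atp_c <-> 2 adp_c	TRUE	-1000	1000	internal
AKGDH	akg_c + coa_c + nad_c -> co2_c + nadh_c + succoa_c	FALSE	0	1000	internal
AKGt2r	akg_e + h_e <-> akg_c + h_c	TRUE	-1000	1000	transport
ATPM	atp_c + h2o_c -> adp_c + h_c + pi_c	FALSE	0	1000	internal
ATPS4r	adp_c + 4 h_e + pi_c <-> atp_c + h2o_c + 3 h_c	TRUE	-1000	1000	internal
Biomass_Ecoli_core	1.496 3pg_c + 3.7477999999999998 accoa_c + 59.810000000000002 atp_c + 0.36099999999999999 e4p_c + 0.070900000000000005 f6p_c + 0.129 g3p_c + 0.20499999999999999 g6p_c + 0.25569999999999998 gln__L_c + 4.9413999999999998 glu__L_c + 59.810000000000002 h2o_c + 3.5470000000000002 nad_c + 13.027900000000001 nadph_c + 1.7867 oaa_c + 0.51910000000000001 pep_c + 2.8328000000000002 pyr_c + 0.89770000000000005 r5p_c -> 59.810000000000002 adp_c + 4.1181999999999999 akg_c + 3.7477999999999998 coa_c + 59.810000000000002 h_c + 3.5470000000000002 nadh_c + 13.027900000000001 nadp_c + 59.810000000000002 pi_c	FALSE	0	1000	biomass
CO2t	co2_e <-> co2_c	TRUE	-1000	1000	transport
CS	accoa_c + h2o_c + oaa_c -> cit_c + coa_c + h_c	FALSE	0	1000	internal
CYTBD	2 h_c + 0.5 o2_c + q8h2_c -> h2o_c + 2 h_e + q8_c	FALSE	0	1000	internal
D_LACt2	h_e + lac__D_e <-> h_c + lac__D_c	TRUE	-1000	1000	transport
ENO	2pg_c <-> h2o_c + pep_c	TRUE	-1000	1000	internal
EX_ac_e	ac_e ->	FALSE	0	1000	exchange
EX_acald_e	acald_e ->	FALSE	0	1000	exchange
EX_akg_e	akg_e <->	FALSE	0	1000	exchange
EX_co2_e	co2_e ->	FALSE	0	1000	exchange
EX_for_e	for_e ->	FALSE	0	1000	exchange
EX_fru_e	fru_e ->	FALSE	0	1000	exchange
EX_fum_e	fum_e ->	FALSE	0	1000	exchange
EX_glc__D_e	glc__D_e ->	FALSE	0	1000	exchange
EX_gln__L_e	gln__L_e ->	FALSE	0	1000	exchange
EX_glu__L_e	glu__L_e ->	FALSE	0	1000	exchange
EX_h_e	h_e <->	FALSE	0	1000	exchange
EX_h2o_e	h2o_e <->	FALSE	0	1000	exchange
EX_lac__D_e	lac__D_e ->	FALSE	0	1000	exchange
EX_mal__L_e	mal__L_e ->	FALSE	0	1000	exchange
EX_nh4_e	nh4_e <->	FALSE	0	1000	exchange
EX_o2_e	o2_e <->	FALSE	0	1000	exchange
EX_pi_e	pi_e <->	FALSE	0	1000	exchange
EX_pyr_e	pyr_e ->	FALSE	0	1000	exchange
EX_succ_e	succ_e ->	FALSE	0	1000	exchange
FBA	fdp_c <-> dhap_c + g3p_c	TRUE	-1000	1000	internal
FBP	fdp_c + h2o_c -> f6p_c + pi_c	FALSE	0	1000	internal
FORt2	for_e + h_e -> for_c + h_c	FALSE	0	1000	transport
FORti	for_c -> for_e	FALSE	0	1000	transport
FRD7	fum_c + q8h2_c -> q8_c + succ_c	FALSE	0	1000	internal
FRUpts2	fru_e + pep_c -> f6p_c + pyr_c	FALSE	0	1000	transport
FUM	fum_c + h2o_c <-> mal__L_c	TRUE	-1000	1000	internal
FUMt2_2	fum_e + 2 h_e -> fum_c + 2 h_c	FALSE	0	1000	transport
G6PDH2r	g6p_c + nadp_c <-> 6pgl_c + h_c + nadph_c	TRUE	-1000	1000	internal
GAPD	g3p_c + nad_c + pi_c <-> 13dpg_c + h_c + nadh_c	TRUE	-1000	1000	internal
GLCpts	glc__D_e + pep_c -> g6p_c + pyr_c	FALSE	0	1000	transport
GLNS	atp_c + glu__L_c + nh4_c -> adp_c + gln__L_c + h_c + pi_c	FALSE	0	1000	internal
GLNabc	atp_c + gln__L_e + h2o_c -> adp_c + gln__L_c + h_c + pi_c	FALSE	0	1000	transport
GLUDy	glu__L_c + h2o_c + nadp_c <-> akg_c + h_c + nadph_c + nh4_c	TRUE	-1000	1000	internal
GLUN	gln__L_c + h2o_c -> glu__L_c + nh4_c	FALSE	0	1000	internal
GLUSy	akg_c + gln__L_c + h_c + nadph_c -> 2 glu__L_c + nadp_c	FALSE	0	1000	internal
GLUt2r	glu__L_e + h_e <-> glu__L_c + h_c	TRUE	-1000	1000	transport
GND	6pgc_c + nadp_c -> co2_c + nadph_c + ru5p__D_c	FALSE	0	1000	internal
H2Ot	h2o_e <-> h2o_c	TRUE	-1000	1000	transport
ICDHyr	icit_c + nadp_c <-> akg_c + co2_c + nadph_c	TRUE	-1000	1000	internal
ICL	icit_c -> glx_c + succ_c	FALSE	0	1000	internal
LDH_D	lac__D_c + nad_c <-> h_c + nadh_c + pyr_c	TRUE	-1000	1000	internal
MALS	accoa_c + glx_c + h2o_c -> coa_c + h_c + mal__L_c	FALSE	0	1000	internal
MALt2_2	2 h_e + mal__L_e -> 2 h_c + mal__L_c	FALSE	0	1000	transport
MDH	mal__L_c + nad_c <-> h_c + nadh_c + oaa_c	TRUE	-1000	1000	internal
ME1	mal__L_c + nad_c -> co2_c + nadh_c + pyr_c	FALSE	0	1000	internal
ME2	mal__L_c + nadp_c -> co2_c + nadph_c + pyr_c	FALSE	0	1000	internal
NADH16	4 h_c + nadh_c + q8_c -> 3 h_e + nad_c + q8h2_c	FALSE	0	1000	internal
NADTRHD	nad_c + nadph_c -> nadh_c + nadp_c	FALSE	0	1000	internal
NH4t	nh4_e <-> nh4_c	TRUE	-1000	1000	transport
O2t	o2_e <-> o2_c	TRUE	-1000	1000	transport
PDH	coa_c + nad_c + pyr_c -> accoa_c + co2_c + nadh_c	FALSE	0	1000	internal
PFK	atp_c + f6p_c -> adp_c + fdp_c + h_c	FALSE	0	1000	internal
PFL	coa_c + pyr_c -> accoa_c + for_c	FALSE	0	1000	internal
PGI	g6p_c <-> f6p_c	TRUE	-1000	1000	internal
PGK	3pg_c + atp_c <-> 13dpg_c + adp_c	TRUE	-1000	1000	internal
PGL	6pgl_c + h2o_c -> 6pgc_c + h_c	FALSE	0	1000	internal
PGM	2pg_c <-> 3pg_c	TRUE	-1000	1000	internal
PIt2r	h_e + pi_e <-> h_c + pi_c	TRUE	-1000	1000	transport
PPC	co2_c + h2o_c + pep_c -> h_c + oaa_c + pi_c	FALSE	0	1000	internal
PPCK	atp_c + oaa_c -> adp_c + co2_c + pep_c	FALSE	0	1000	internal
PPS	atp_c + h2o_c + pyr_c -> amp_c + 2 h_c + pep_c + pi_c	FALSE	0	1000	internal
PTAr	accoa_c + pi_c <-> actp_c + coa_c	TRUE	-1000	1000	internal
PYK	adp_c + h_c + pep_c -> atp_c + pyr_c	FALSE	0	1000	internal
PYRt2	h_e + pyr_e <-> h_c + pyr_c	TRUE	-1000	1000	transport
RPE	ru5p__D_c <-> xu5p__D_c	TRUE	-1000	1000	internal
RPI	r5p_c <-> ru5p__D_c	TRUE	-1000	1000	internal
SUCCt2_2	2 h_e + succ_e -> 2 h_c + succ_c	FALSE	0	1000	transport
SUCCt3	h_e + succ_c -> h_c + succ_e	FALSE	0	1000	transport
SUCDi	q8_c + succ_c -> fum_c + q8h2_c	FALSE	0	1000	internal
SUCOAS	atp_c + coa_c + succ_c <-> adp_c + pi_c + succoa_c	TRUE	-1000	1000	internal
TALA	g3p_c + s7p_c <-> e4p_c + f6p_c	TRUE	-1000	1000	internal
THD2	2 h_e + nadh_c + nadp_c -> 2 h_c + nad_c + nadph_c	FALSE	0	1000	internal
TKT1	r5p_c + xu5p__D_c <-> g3p_c + s7p_c	TRUE	-1000	1000	internal
TKT2	e4p_c + xu5p__D_c <-> f6p_c + g3p_c	TRUE	-1000	1000	internal
TPI	dhap_c <-> g3p_c	TRUE	-1000	1000	internal
ACONT	cit_c <-> icit_c	TRUE	-1000	1000	internal
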