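# minimal environments: one sole carbon source + shared nutrients, uptake bound 10
environment	exchange	bound	role
acetate	EX_ac_e	10	carbon
acetate	EX_o2_e	10	shared
acetate	EX_nh4_e	10	shared
acetate	EX_pi_e	10	shared
acetate	EX_h2o_e	10	shared
acetate	EX_h_e	10	shared
alpha-ketoglutarate	EX_akg_e	10	carbon
alpha-ketoglutarate	EX_o2_e	10	shared
alpha-ketoglutarate	EX_nh4_e	10	shared
alpha-ketoglutarate	EX_pi_e	10	shared
alpha-ketoglutarate	EX_h2o_e	10	shared
alpha-ketoglutarate	EX_h_e	10	shared
fumarate	EX_fum_e	10	carbon
fumarate	EX_o2_e	10	shared
fumarate	EX_nh4_e	10	shared
fumarate	EX_pi_e	10	shared
fumarate	EX_h2o_e	10	shared
fumarate	EX_h_e	10	shared
fructose	EX_fru_e	10	carbon
fructose	EX_o2_e	10	shared
fructose	EX_nh4_e	10	shared
fructose	EX_pi_e	10	shared
fructose	EX_h2o_e	10	shared
fructose	EX_h_e	10	shared
glucose	EX_glc__D_e	10	carbon
glucose	EX_o2_e	10	shared
glucose	EX_nh4_e	10	shared
glucose	EX_pi_e	10	shared
glucose	EX_h2o_e	10	shared
glucose	EX_h_e	10	shared
glutamate	EX_glu__L_e	10	carbon
glutamate	EX_o2_e	10	shared
glutamate	EX_nh4_e	10	shared
glutamate	EX_pi_e	10	shared
glutamate	EX_h2o_e	10	shared
glutamate	EX_h_e	10	shared
lactate	EX_lac__D_e	10	carbon
lactate	EX_o2_e	10	shared
lactate	EX_nh4_e	10	shared
lactate	EX_pi_e	10	shared
lactate	EX_h2o_e	10	shared
lactate	EX_h_e	10	shared
malate	EX_mal__L_e	10	carbon
malate	EX_o2_e	10	shared
malate	EX_nh4_e	10	shared
malate	EX_pi_e	10	shared
malate	EX_h2o_e	10	shared
malate	EX_h_e	10	shared
pyruvate	EX_pyr_e	10	carbon
pyruvate	EX_o2_e	10	shared
pyruvate	EX_nh4_e	10	shared
pyruvate	EX_pi_e	10	shared
pyruvate	EX_h2o_e	10	shared
pyruvate	EX_h_e	10	shared
succinate	EX_succ_e	10	carbon
succinate	EX_o2_e	10	shared
succinate	EX_nh4_e	10	shared
succinate	EX_pi_e	10	shared
succinate	EX_h2o_e	10	shared
succinate	EX_h_e	10	shared
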