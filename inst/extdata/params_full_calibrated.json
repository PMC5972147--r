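{
  "schema_version": 1,
  "variant": "FULL",
  "parameters": {
    "b_smad": 0.0240838633548151,
    "k_smad": 0.115450450743748,
    "K_r": 0.875803647860003,
    "n_r": 4,
    "K_i": 1.87980561144179,
    "d_smad": 0.119651700480568,
    "b_ismad": 0.0352013672261879,
    "k_ismad": 0.193927423273663,
    "K_si": 0.420345995967057,
    "d_ismad": 0.0650943520095185,
    "b_snm": 0.0131366092667122,
    "a_snm_s": 0.371031023733064,
    "K_snm_s": 1.24567500416204,
    "d_snm": 0.106281141089902,
    "k_snp": 5.39601230705726,
    "d_snp": 0.297800215685815,
    "k_on": 0.245067022661804,
    "k_off": 0.0657766066683592,
    "k_s_on": 0.298392238150734,
    "k_s_off": 0.0216799463561557,
    "w_s": 2.84500963319225,
    "n_h": 4,
    "ismad_scale": 1,
    "a_snm_g": 0.178943695798964,
    "K_snm_g": 0.447503696616866,
    "b_glm": 0.0129527093832844,
    "a_glm_s": 0.159860437783993,
    "K_glm_s": 0.00984601609143048,
    "a_glm_g": 2.33825986294598,
    "K_glm_g": 0.115987778872295,
    "d_glm": 0.889939641577137,
    "k_glb": 0.282277209186795,
    "d_glc": 0.0273263065738159,
    "kg_glc": 0.0651755544252137,
    "r_rel0": 0.000412680087431511,
    "k_rel": 5.03624738238052,
    "k_imp": 2.40492917818177,
    "d_gln": 0.74523305897477,
    "kg_gln": 3.21620105209309,
    "kg_snp": 13.1533772043574,
    "frac_aa0": 0.1,
    "frac_d0": 0.37,
    "m_nuc": 1,
    "m_cyt": 1,
    "glm_scale": 1,
    "k_aa_u": 0.0865754167299551,
    "k_aa_r": 0.392874890387474,
    "k_d_u": 0.326090578885832,
    "K_ds": 0.357187466957563,
    "k_d_r": 0.0893378598660924
  }
}
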