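protein_id,recruitment_class,flagellum_bias,conservation,rnai_phenotype
FBF1,before_duplication,equal,beyond_kinetoplastids,assembly_defect
TFP104,before_duplication,old_enriched,kinetoplastid_only,length_defect
TFP101,before_duplication,equal,beyond_kinetoplastids,untested
TFP61,before_duplication,equal,kinetoplastid_only,untested
TFP39,before_duplication,old_enriched,kinetoplastid_only,none
TFP59,before_duplication,equal,kinetoplastid_only,untested
TFP49,before_duplication,equal,kinetoplastid_only,length_defect
TFP64,before_duplication,equal,kinetoplastid_only,untested
BBP96,before_duplication,equal,kinetoplastid_only,untested
BBP86,before_duplication,equal,kinetoplastid_only,untested
TFP123,before_duplication,equal,kinetoplastid_only,none
TFP131,before_duplication,equal,kinetoplastid_only,untested
TFP17,before_duplication,equal,kinetoplastid_only,none
TFP72,before_duplication,new_enriched,kinetoplastid_only,none
TFP82,before_duplication,equal,beyond_kinetoplastids,untested
CEP164A,after_duplication,equal,beyond_kinetoplastids,untested
TFP68,after_duplication,equal,kinetoplastid_only,assembly_defect
TFP52,after_duplication,equal,kinetoplastid_only,none
CEP19,after_duplication,equal,beyond_kinetoplastids,assembly_defect
TFP32,after_duplication,equal,kinetoplastid_only,untested
TFP62,after_duplication,equal,kinetoplastid_only,none
ARL3C,after_duplication,equal,kinetoplastid_only,untested
SPB1,after_duplication,equal,beyond_kinetoplastids,none
CEP164B,after_duplication,equal,kinetoplastid_only,untested
RABL2B,after_duplication,old_enriched,beyond_kinetoplastids,assembly_defect
CUL4B,after_duplication,equal,kinetoplastid_only,growth_defect_only
TFP122,after_duplication,old_enriched,kinetoplastid_only,length_defect
CEP164C,after_duplication,equal,kinetoplastid_only,untested
CEP90,probasal,equal,beyond_kinetoplastids,assembly_defect
OFD1,probasal,equal,beyond_kinetoplastids,assembly_defect
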