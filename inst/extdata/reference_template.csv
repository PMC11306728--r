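"compound","value","parameter"
"example_drug_1",0.001,"Kd_uM"
"example_drug_2",0.02,"Kd_uM"
"example_drug_1",1.2,"koff_per_h"
"example_drug_1",0.31,"fu"
"example_drug_1",18,"CL_L_per_h"
"example_drug_1",4.5,"bioavailable_dose_mg"
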