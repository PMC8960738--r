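"variable","value"
"v",-77.3748378718901
"m",0.00541508423006152
"h",0.920872267510193
"j",0.9415276528458
"d",0.000117746990064486
"f",0.999220359678757
"fca",0.846007167123701
"ua",0.00736496177955206
"uif",0.998398081796806
"uis",0.998425697750251
"xr",0.000155436425862843
"xs",0.0223156349912322
"qca",0
"u",9.65567535313615e-113
"v_rel",1
"w",0.999999990897227
"nai",7.8303227141106
"ki",142.454418856092
"cai",6.37080139945981e-05
"caup",0.973312360823085
"carel",0.973616329892196
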