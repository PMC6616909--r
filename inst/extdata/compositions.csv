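label,sugar,ash,fiber,starch,protein,oil
C. morifolium flower,0.4923,0.077,0.13384,0.07692,0.1892,0.0311
A. formosanus Hayata,0.098,0.02,0.23,0.0,0.07,0.01
Raw bamboo,0.1964,0.1265,0.1429,0.4688,0.0045,0.0
Elecampe,0.0,0.053,0.01,0.874,0.0775,0.0
Corn VR,0.03965,0.01925,0.03579,0.75185,0.11147,0.04199
Corn VN,0.01508,0.01607,0.03946,0.77221,0.10573,0.05144
Corn VA,0.02674,0.015394,0.036445,0.73766,0.12969,0.05408
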