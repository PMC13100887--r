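class	resistance
Buildings	ABS
Path	14
Waterbodies	ABS
Railways	100
Small street	8
Highways	100
Large street	100
Linear Water	100
Wetland	100
Impervious	13
Woodland	100
Lawn	5
Amenity	6
Parks and Playspace	1
Cemeteries	1
Allotments	1
Farmland	100
Private Garden	1
Unclassified	15
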