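source	ids_encoded	extensions_used	instances_encoded	extension_instances
Administrative stay	1172	2	78020550	131832
Anesthesiology	2139	11	117419522	1275337
Medical devices	699	235	4926815	1140820
Formularies	51322	3925	1641633208	119941273
ICU	6934	157	6656119500	367548
Laboratory	7231	72	935678204	250617656
Observations	2784	1	2440891370	1003
Patient problems	25233	72	1587507	976
Prescription	9837	0	26805381	0
Radiology	2586	2	8562371	2
Procedures	8001	23	1452038108	8934163
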