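attribute	domain	range	cardinality	groupable
45169001	<< 404684003 OR << 71388002	<< 260787004 OR << 404684003 OR << 71388002	optional-many	TRUE
5185003	<< 404684003 OR << 71388002	<< 260787004 OR << 404684003 OR << 71388002	optional-many	TRUE
408729009	<< 243796009 OR << 404684003	<< 362981000	optional-many	TRUE
408730004	<< 243796009 OR << 71388002	<< 362981000	optional-many	TRUE
103373006	<< 260787004 OR << 71388002	num	optional-many	TRUE
410671006	<< 404684003 OR << 71388002	date	optional-many	TRUE
79409006	<< 404684003 OR << 71388002	num	optional-many	TRUE
246205007	<< 404684003 OR << 71388002 OR << 260787004	num	optional-many	TRUE
246262008	<< 404684003 OR << 363787002	num	optional-many	TRUE
255234002	<< 404684003 OR << 71388002	<< 404684003 OR << 71388002 OR date	optional-many	TRUE
288556008	<< 404684003 OR << 71388002	<< 404684003 OR << 71388002 OR date	optional-many	TRUE
371881003	<< 404684003 OR << 71388002	<< 404684003 OR << 71388002 OR date	optional-many	TRUE
103335007	<< 404684003 OR << 71388002	num	optional-many	TRUE
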