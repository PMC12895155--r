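attribute	domain	range	cardinality	groupable
408729009	<< 243796009	<< 362981000	optional-many	TRUE
408730004	<< 243796009	<< 362981000	optional-many	TRUE
255234002	<< 404684003	<< 404684003 OR << 71388002	optional-many	TRUE
288556008	<< 404684003	<< 404684003	optional-many	TRUE
371881003	<< 404684003	<< 404684003	optional-many	TRUE
363698007	<< 404684003	<< 123037004	optional-many	TRUE
260686004	<< 71388002	<< 362981000	optional-many	TRUE
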