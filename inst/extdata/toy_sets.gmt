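SMELL	sensory perception of smell	ALPHA	BETA	GAMMA	DELTA
ANTIGEN	antigen processing and presentation	ETA	THETA	LAMBDA
HOUSEKEEPING	control set	ZETA	EPSILON	ALPHA
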